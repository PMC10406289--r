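define MRI sequence "Example 1"
  using a "SpinEcho" with "EPIReadout".
Specify echo
  as excitation
    with type sincpulse and angle 90,
  and refocussing
    with type sincpulse and angle 180.
Specify readout
  with duration 500
  and number-of-columns 32.
Specify timing parameters
  with TE 46
  and TR 5014.
Specify trajectory
  with Epi-Factor 32
  and ETL 1
  and number-of-rows 32.
Specify measurements
  with count 10.
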