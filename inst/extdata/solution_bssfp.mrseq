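define MRI sequence "Example 2"
  using a "GradientEcho" with "LineReadout".
Specify echo
  as excitation
    with type sincpulse and angle 90,
Specify readout
  with duration 2000
  and number-of-columns 64.
Specify timing parameters
  with TE 17
  and TR 36.
Specify trajectory
  with Epi-Factor 1
  and ETL 1
  and number-of-rows 64.
Specify measurements
  with count 2.
Add prescans
  with count 8.
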