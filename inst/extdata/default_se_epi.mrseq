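define MRI sequence "SE-EPI-default"
  using a "SpinEcho" with "EPIReadout".
Specify echo
  as excitation
    with type sincpulse and angle 90,
  and refocussing
    with type sincpulse and angle 180.
Specify readout
  with duration 500
  and number-of-columns 64.
Add gradient spoiling around refocussing
  of type balanced.
Add gradient spoiling after segment.
Specify timing parameters
  with TE 50
  and TR 1000.
Specify trajectory
  with Epi-Factor 64
  and ETL 1
  and number-of-rows 64.
Specify measurements
  with count 10.
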