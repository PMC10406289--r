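define MRI sequence "RARE-default"
  using a "SpinEcho" with "LineReadout".
Add gradient spoiling around refocussing
  of type balanced.
Add gradient spoiling after echotrain.
Specify echo
  as excitation
    with type sincpulse and angle 90,
  and refocussing
    with type sincpulse and angle 180.
Specify readout
  with duration 2000
  and number-of-columns 64.
Specify timing parameters
  with TE 44
  and TR 500.
Specify trajectory
  with Epi-Factor 1
  and ETL 8
  and number-of-rows 64.
Specify measurements
  with count 1.
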