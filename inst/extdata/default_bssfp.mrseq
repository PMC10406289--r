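Define MRI sequence "bSSFP"
  using a "GradientEcho" with "LineReadout".
Add prescans
  with count 8 and type linear.
Specify echo
  as excitation
    with type sincpulse and angle 90.
Specify readout
  with duration 2000
  and number-of-columns 64.
Add gradient spoiling around readout
  of type balanced.
Specify timing parameters
  with TE 4
  and TR 8.
Specify trajectory
  with Epi-Factor 1
  and ETL 1
  and number-of-rows 64.
Specify measurements
  with count 1.
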