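Define MRI sequence "EPI-default"
   using a "GradientEcho" with "EPIReadout".
Specify echo
  as excitation
    with type sincpulse and angle 90.
Specify readout
  with duration 500
  and number-of-columns 64.
Add gradient spoiling after segment.
Specify timing parameters
  with TE 35
  and TR 1000.
Specify trajectory
  with Epi-Factor 64
  and ETL 1
  and number-of-rows 64.
Specify measurements
  with count 10.
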