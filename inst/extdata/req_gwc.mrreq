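define optimization requirement :
  maximize "GWC".
  obey the following constraints:
    "SNR_GM" is higher than 30.
    "SNR_WM" is higher than 30.
    "SNR_GM" is higher than "SNR_WM".
  aim for the following :
    avoid "ghosting".
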