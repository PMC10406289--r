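define optimization requirement :
  maximize "SNR_CSF".
  obey the following constraints:
   "Sharpness" is higher than 0.85.
  aim for the following :
    avoid "ghosting".
    avoid "motion".
    avoid "distortion".
    have high "CGC".
    have high "CWC".
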