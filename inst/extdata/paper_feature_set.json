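[
  "t1post_hist_kurtosis",
  "t1post_ngtdm_contrast",
  "t1post_glszm_small_zone_emphasis",
  "t1post_glszm_low_gray_zone_emphasis",
  "t1post_glszm_high_gray_zone_emphasis",
  "t1post_glszm_small_zone_high_gray_emphasis"
]
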