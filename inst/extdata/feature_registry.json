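["t1post_hist_mean", "t1post_hist_variance", "t1post_hist_skewness", "t1post_hist_kurtosis", "t1post_hist_entropy", "t1post_hist_uniformity", "t1post_glcm_energy", "t1post_glcm_contrast", "t1post_glcm_correlation", "t1post_glcm_sum_of_squares", "t1post_glcm_homogeneity", "t1post_glcm_sum_average", "t1post_glcm_sum_variance", "t1post_glcm_sum_entropy", "t1post_glcm_entropy", "t1post_glcm_difference_variance", "t1post_glcm_difference_entropy", "t1post_glcm_imc1", "t1post_glcm_imc2", "t1post_glcm_autocorrelation", "t1post_glcm_cluster_shade", "t1post_glcm_cluster_prominence", "t1post_glcm_cluster_tendency", "t1post_glcm_dissimilarity", "t1post_glcm_max_probability", "t1post_ngtdm_coarseness", "t1post_ngtdm_contrast", "t1post_ngtdm_busyness", "t1post_ngtdm_complexity", "t1post_ngtdm_strength", "t1post_glszm_small_zone_emphasis", "t1post_glszm_large_zone_emphasis", "t1post_glszm_gray_level_nonuniformity", "t1post_glszm_zone_size_nonuniformity", "t1post_glszm_zone_percentage", "t1post_glszm_low_gray_zone_emphasis", "t1post_glszm_high_gray_zone_emphasis", "t1post_glszm_small_zone_low_gray_emphasis", "t1post_glszm_small_zone_high_gray_emphasis", "t1post_glszm_large_zone_low_gray_emphasis", "t1post_glszm_large_zone_high_gray_emphasis", "t1post_regional_volume_mm3", "t1post_regional_total_intensity", "flair_hist_mean", "flair_hist_variance", "flair_hist_skewness", "flair_hist_kurtosis", "flair_hist_entropy", "flair_hist_uniformity", "flair_glcm_energy", "flair_glcm_contrast", "flair_glcm_correlation", "flair_glcm_sum_of_squares", "flair_glcm_homogeneity", "flair_glcm_sum_average", "flair_glcm_sum_variance", "flair_glcm_sum_entropy", "flair_glcm_entropy", "flair_glcm_difference_variance", "flair_glcm_difference_entropy", "flair_glcm_imc1", "flair_glcm_imc2", "flair_glcm_autocorrelation", "flair_glcm_cluster_shade", "flair_glcm_cluster_prominence", "flair_glcm_cluster_tendency", "flair_glcm_dissimilarity", "flair_glcm_max_probability", "flair_ngtdm_coarseness", "flair_ngtdm_contrast", "flair_ngtdm_busyness", "flair_ngtdm_complexity", "flair_ngtdm_strength", "flair_glszm_small_zone_emphasis", "flair_glszm_large_zone_emphasis", "flair_glszm_gray_level_nonuniformity", "flair_glszm_zone_size_nonuniformity", "flair_glszm_zone_percentage", "flair_glszm_low_gray_zone_emphasis", "flair_glszm_high_gray_zone_emphasis", "flair_glszm_small_zone_low_gray_emphasis", "flair_glszm_small_zone_high_gray_emphasis", "flair_glszm_large_zone_low_gray_emphasis", "flair_glszm_large_zone_high_gray_emphasis", "flair_regional_volume_mm3", "flair_regional_total_intensity"]
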