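test_that("histogram features match direct moment computation", {
  q <- qroi(array(1:4, dim = c(4, 1, 1)), G = 4)
  f <- histogram_features(q)
  expect_equal(unname(f["hist_mean"]), 2.5)
  expect_equal(unname(f["hist_variance"]), 1.25)
  expect_equal(unname(f["hist_skewness"]), 0)
  expect_equal(unname(f["hist_kurtosis"]), 1.64)  # m4/m2^2, Pearson
  expect_equal(unname(f["hist_entropy"]), 2)      # 4 equiprobable levels
  expect_equal(unname(f["hist_uniformity"]), 0.25)
})

test_that("equiprobable 8-level histogram has 3 bits entropy, uniformity 1/8", {
  q <- qroi(array(rep(1:8, 3), dim = c(24, 1, 1)), G = 8)
  f <- histogram_features(q)
  expect_equal(unname(f["hist_entropy"]), 3)
  expect_equal(unname(f["hist_uniformity"]), 0.125)
})

test_that("constant ROI histogram is degenerate: variance 0, uniformity 1", {
  q <- qroi(array(1L, dim = c(3, 3, 3)), G = 8)
  f <- histogram_features(q)
  expect_equal(unname(f["hist_variance"]), 0)
  expect_equal(unname(f["hist_uniformity"]), 1)
  expect_equal(unname(f["hist_skewness"]), 0)
  expect_equal(unname(f["hist_kurtosis"]), 0)
  expect_true(isTRUE(attr(f, "degenerate")))
})

test_that("co-occurrence features on a 1D alternating strip match the hand oracle", {
  # [1,2,1,2] along x: 3 pairs, symmetric -> p(1,2) = p(2,1) = 1/2
  q <- qroi(array(c(1L, 2L, 1L, 2L), dim = c(4, 1, 1)), G = 2)
  f <- gtsdm_features(q)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_energy"]), 0.5)
  expect_equal(unname(f["glcm_max_probability"]), 0.5)
  expect_equal(unname(f["glcm_dissimilarity"]), 1)
})

test_that("constant ROI co-occurrence is the single-cell matrix", {
  q <- qroi(array(1L, dim = c(3, 3, 2)), G = 8)
  f <- gtsdm_features(q)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_max_probability"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 1)  # documented sentinel
  expect_true(isTRUE(attr(f, "degenerate")))
})

test_that("pooled co-occurrence matrix is symmetric and sums to 1", {
  for (s in 1:5) {
    lev <- random_quantized(s, G = 5)
    M <- cd3radiomics:::cpp_glcm(as.integer(lev), dim(lev), 5L)
    if (sum(M) == 0) next
    P <- M / sum(M)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("NGTDM features on a 3x3 toy with one deviant center match the formula", {
  lev <- array(1L, dim = c(3, 3, 1))
  lev[2, 2, 1] <- 2L
  q <- qroi(lev, G = 2)
  f <- ngtdm_features(q)
  # hand evaluation: s_1 = 4/3 + 4/5, s_2 = 1, p = (8/9, 1/9)
  expect_equal(unname(f["ngtdm_contrast"]), 376 / 10935)
  expect_equal(unname(f["ngtdm_coarseness"]), 135 / 271)
})

test_that("constant ROI NGTDM: contrast and busyness 0, coarseness capped", {
  q <- qroi(array(1L, dim = c(4, 4, 2)), G = 8)
  f <- ngtdm_features(q)
  expect_equal(unname(f["ngtdm_contrast"]), 0)
  expect_equal(unname(f["ngtdm_busyness"]), 0)
  expect_equal(unname(f["ngtdm_coarseness"]), 1e6)
})

test_that("GLSZM features on the 3x3 three-zone grid match the exhaustive oracle", {
  lev <- array(c(1L, 1L, 3L,  1L, 2L, 3L,  2L, 2L, 3L), dim = c(3, 3, 1))
  # rows of the spec grid [[1,1,2],[1,2,2],[3,3,3]] laid out column-major
  q <- qroi(lev, G = 3)
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_small_zone_emphasis"]), 1 / 9)
  expect_equal(unname(f["glszm_high_gray_zone_emphasis"]), 14 / 3)
  expect_equal(unname(f["glszm_low_gray_zone_emphasis"]), 49 / 108)
  expect_equal(unname(f["glszm_zone_percentage"]), 3 / 9)
  # agreement with the naive flood-fill oracle on the same grid
  expect_equal(f, oracle_glszm_features(lev))
})

test_that("constant ROI is one zone with zone percentage 1/N", {
  lev <- array(1L, dim = c(4, 3, 2))
  f <- glszm_features(qroi(lev, G = 2))
  expect_equal(unname(f["glszm_zone_percentage"]), 1 / 24)
  expect_equal(unname(f["glszm_large_zone_emphasis"]), 24^2)
})

test_that("regional features are sums over the mask and behave linearly", {
  masks <- toy_masks()
  vol <- toy_volume(2)
  f <- regional_features(vol, masks$tumor)
  n <- sum(masks$tumor$mask)
  expect_equal(unname(f["regional_volume_mm3"]), n)
  expect_equal(unname(f["regional_total_intensity"]), 2 * n)
  # doubling intensity doubles the total, not the volume
  f2 <- regional_features(toy_volume(4), masks$tumor)
  expect_equal(unname(f2["regional_total_intensity"]), 4 * n)
  expect_equal(unname(f2["regional_volume_mm3"]), n)
  # voxels outside the mask are irrelevant
  vals <- vol$values
  vals[!masks$tumor$mask] <- 999
  f3 <- regional_features(volume_image(vals, vol$spacing, "t1post"),
                          masks$tumor)
  expect_equal(f3, f)
})

test_that("extract_all yields exactly 86 finite features with the family counts", {
  f <- extract_all(small_patient(4))
  expect_length(f, 86)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), feature_names())
  for (mod in c("t1post", "flair")) {
    counts <- c(hist = 6, glcm = 19, ngtdm = 5, glszm = 11, regional = 2)
    for (fam in names(counts))
      expect_length(grep(paste0("^", mod, "_", fam, "_"), names(f)),
                    counts[[fam]])
    expect_length(grep(paste0("^", mod, "_"), names(f)), 43)
  }
})

test_that("identical modality inputs give pairwise equal feature values", {
  ph <- small_patient(6)
  ph$flair <- volume_image(ph$t1post$values, ph$t1post$spacing, "flair")
  ph$tumor_flair <- ph$tumor_t1post
  f <- extract_all(ph)
  t1 <- f[grep("^t1post_", names(f))]
  fl <- f[grep("^flair_", names(f))]
  expect_equal(unname(t1), unname(fl))
})

test_that("extract_all rejects records missing a modality or mask", {
  ph <- small_patient(1)
  ph$flair <- NULL
  expect_error(extract_all(ph), "missing modality")
  ph2 <- small_patient(1)
  ph2$tumor <- NULL
  ph2$tumor_t1post <- NULL
  expect_error(extract_all(ph2), "masks")
})

test_that("texture features are invariant to rigid whole-voxel translation", {
  set.seed(41)
  lev <- array(0L, dim = c(12, 12, 8))
  lev[3:7, 3:7, 2:5] <- sample.int(6, 100, replace = TRUE)
  shifted <- array(0L, dim = c(12, 12, 8))
  shifted[6:10, 5:9, 4:7] <- lev[3:7, 3:7, 2:5]
  fa <- c(histogram_features(qroi(lev, G = 6)),
          gtsdm_features(qroi(lev, G = 6)),
          ngtdm_features(qroi(lev, G = 6)),
          glszm_features(qroi(lev, G = 6)))
  fb <- c(histogram_features(qroi(shifted, G = 6)),
          gtsdm_features(qroi(shifted, G = 6)),
          ngtdm_features(qroi(shifted, G = 6)),
          glszm_features(qroi(shifted, G = 6)))
  expect_equal(fa, fb)
})
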