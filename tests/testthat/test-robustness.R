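make_solid_mask <- function() {
  m <- array(FALSE, dim = c(20L, 20L, 8L))
  m[6:14, 6:14, 3:6] <- TRUE
  roi_mask(m, "tumor")
}

test_that("the eight perturbation kinds produce eight distinct nonempty masks", {
  ph <- small_patient(3)
  prep <- preprocess_modality(ph$t1post, ph$tumor, ph$nawm)
  masks <- lapply(perturbation_kinds(),
                  function(k) perturb_mask(prep$tumor, k, seed = 5))
  expect_length(masks, 8)
  for (m in masks) expect_gt(sum(m$mask), 0)
  keys <- vapply(masks, function(m) paste(which(m$mask), collapse = ","), "")
  expect_length(unique(keys), 8)
})

test_that("translation is exactly invertible", {
  m <- make_solid_mask()
  t1 <- perturb_mask(m, "translate_h")
  back <- cd3radiomics:::shift_mask(t1$mask, -2L)
  expect_identical(back, m$mask)
  t2 <- perturb_mask(m, "translate_hv")
  back2 <- cd3radiomics:::shift_mask(t2$mask, -2L, -2L)
  expect_identical(back2, m$mask)
})

test_that("dilation grows and erosion shrinks a solid mask strictly", {
  m <- make_solid_mask()
  expect_gt(sum(perturb_mask(m, "dilate_1")$mask), sum(m$mask))
  expect_lt(sum(perturb_mask(m, "erode_1")$mask), sum(m$mask))
  # erosion of a 1-voxel mask empties it and must be rejected
  tiny <- array(FALSE, dim = c(5L, 5L, 5L))
  tiny[3, 3, 3] <- TRUE
  expect_error(perturb_mask(roi_mask(tiny, "tumor"), "erode_1"), "emptied")
})

test_that("jitter is deterministic under its seed and needs one", {
  m <- make_solid_mask()
  a <- perturb_mask(m, "jitter_sd0.5", seed = 42)
  b <- perturb_mask(m, "jitter_sd0.5", seed = 42)
  expect_identical(a$mask, b$mask)
  expect_error(perturb_mask(m, "jitter_sd0.5"), "seed")
  # sd 0.1 rarely moves anything; sd 0.5 perturbs more voxels
  d01 <- sum(xor(perturb_mask(m, "jitter_sd0.1", seed = 1)$mask, m$mask))
  d05 <- sum(xor(perturb_mask(m, "jitter_sd0.5", seed = 1)$mask, m$mask))
  expect_lte(d01, d05)
})

test_that("rotation keeps the mask near its original size", {
  m <- make_solid_mask()
  r1 <- perturb_mask(m, "rotate_1deg")
  r5 <- perturb_mask(m, "rotate_5deg")
  expect_lt(abs(sum(r1$mask) - sum(m$mask)) / sum(m$mask), 0.1)
  expect_lt(abs(sum(r5$mask) - sum(m$mask)) / sum(m$mask), 0.1)
})

test_that("ICC(1,1) matches its ANOVA definition on hand cases", {
  # identical versions per subject, subjects differ -> MSW = 0 -> ICC 1
  v <- matrix(c(1, 1, 1, 5, 5, 5, 9, 9, 9), nrow = 3, byrow = TRUE)
  expect_equal(icc(v), 1)
  expect_equal(icc(matrix(c(1, 1, 3, 3), 2, byrow = TRUE)), 1)
  # zero total variance is defined as 1 with a flag
  z <- icc(matrix(2, 4, 3))
  expect_equal(as.numeric(z), 1)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("ICC of subject-independent noise is near 0 and scale invariant", {
  set.seed(9)
  v <- matrix(rnorm(50 * 9), 50, 9)
  est <- icc(v)
  expect_lt(abs(est), 0.15)
  expect_equal(icc(3 * v + 10), est)
  # strong subject effect -> high ICC
  vs <- v * 0.1 + rnorm(50) * 2
  expect_gt(icc(vs), 0.9)
})

test_that("robust_features retains invariant features and drops fresh noise", {
  set.seed(21)
  n <- 30
  base_volume <- runif(n, 50, 150)
  stable <- runif(n, 1, 2)
  versions <- lapply(1:9, function(v) {
    data.frame(volume = base_volume,             # translation-invariant
               stable = stable + rnorm(n, 0, 0.01),
               noise = rnorm(n))                 # fresh noise per version
  })
  out <- robust_features(versions, threshold = 0.6)
  expect_true(all(c("volume", "stable") %in% out$retained))
  expect_false("noise" %in% out$retained)
  expect_equal(out$report$icc[out$report$feature == "volume"], 1)
  # retained set is monotone nonincreasing in the threshold
  r_lo <- robust_features(versions, threshold = 0.3)$retained
  r_hi <- robust_features(versions, threshold = 0.9)$retained
  expect_true(all(r_hi %in% r_lo))
})

test_that("a pure-noise feature is excluded at threshold 0.6 across seeds", {
  excluded <- vapply(1:20, function(s) {
    set.seed(s)
    versions <- lapply(1:9, function(v) data.frame(noise = rnorm(30)))
    !("noise" %in% robust_features(versions, threshold = 0.6)$retained)
  }, TRUE)
  expect_gte(mean(excluded), 0.95)
})

test_that("identical re-measurement gives ICC 1 for every feature", {
  ph <- small_patient(8)
  f <- extract_all(ph)
  versions <- lapply(1:9, function(v) as.data.frame(t(f)))
  # two pseudo-subjects so between-subject variance exists
  f2 <- extract_all(small_patient(9))
  versions <- lapply(versions, function(v) rbind(v, as.data.frame(t(f2))))
  out <- robust_features(versions, threshold = 0.6)
  expect_true(all(out$report$icc == 1))
  expect_equal(sort(out$retained), sort(feature_names()))
})
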