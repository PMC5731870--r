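test_that("a phantom is bitwise reproducible from its seed", {
  sp <- small_phantom_spec(seed = 99)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$t1post$values, b$t1post$values)
  expect_identical(a$flair$values, b$flair$values)
  expect_identical(a$tumor$mask, b$tumor$mask)
})

test_that("degenerate texture reduces to base intensity plus rim", {
  tp <- default_texture_params()
  tp$t1post$noise_sd <- 0
  tp$t1post$grf_amp <- 0
  ph <- generate_phantom(small_phantom_spec(seed = 3, texture_params = tp))
  vals <- ph$t1post$values[ph$tumor$mask]
  base <- tp$t1post$base
  # every tumor voxel is base + a rim term in [0, rim_amp]
  expect_true(all(vals >= base - 1e-9))
  expect_true(all(vals <= base + tp$t1post$rim_amp + 1e-9))
  # the rim term concentrates at the boundary: the deepest voxel carries far
  # less enhancement than the outermost
  expect_lt(min(vals) - base, 0.15 * tp$t1post$rim_amp)
  expect_gt(max(vals) - base, 5 * (min(vals) - base))
  # and with rim off too, the ROI is exactly constant
  tp$t1post$rim_amp <- 0
  ph2 <- generate_phantom(small_phantom_spec(seed = 3, texture_params = tp))
  expect_true(all(ph2$t1post$values[ph2$tumor$mask] == base))
})

test_that("ellipsoid tumor volume matches the analytic value within 5%", {
  sp <- phantom_spec(grid_shape = c(40L, 40L, 40L), spacing_mm = c(1, 1, 1),
                     tumor_center_mm = c(20, 20, 20),
                     tumor_semiaxes_mm = c(10, 10, 10),
                     nawm_center_mm = c(4, 4, 4), nawm_radius_mm = 3,
                     seed = 1)
  ph <- generate_phantom(sp)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(sum(ph$tumor$mask) - analytic) / analytic, 0.05)
})

test_that("tumor and NAWM masks are disjoint and nonempty, and overlap is rejected", {
  ph <- small_patient(5)
  expect_gt(sum(ph$tumor$mask), 0)
  expect_gt(sum(ph$nawm$mask), 0)
  expect_false(any(ph$tumor_flair$mask & ph$nawm$mask))
  expect_false(any(ph$tumor$mask & ph$nawm$mask))
  # the FLAIR ROI strictly contains the T1 ROI (edema margin)
  expect_true(all(ph$tumor_flair$mask[ph$tumor$mask]))
  expect_gt(sum(ph$tumor_flair$mask), sum(ph$tumor$mask))
  sp <- small_phantom_spec(seed = 1)
  sp$nawm_center_mm <- sp$tumor_center_mm
  expect_error(generate_phantom(sp), "overlap")
})

test_that("a cohort is deterministic under its seed, including the written CSV", {
  cs <- small_cohort_spec(n = 4, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(cs, dir = d1)
  c2 <- generate_cohort(cs, dir = d2)
  expect_identical(c1$data$cd3_z, c2$data$cd3_z)
  expect_identical(c1$patients[[2]]$t1post$values, c2$patients[[2]]$t1post$values)
  m1 <- readLines(file.path(d1, "manifest.csv"))
  m2 <- readLines(file.path(d2, "manifest.csv"))
  expect_identical(gsub(d1, "", m1, fixed = TRUE),
                   gsub(d2, "", m2, fixed = TRUE))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a noiseless identity link makes CD3 perfectly rank-correlated with its parameter", {
  cs <- small_cohort_spec(n = 25, seed = 11,
                          cd3_link = list(coef = c(t1post_grf_clen_mm = 1),
                                          noise_sd = 0))
  co <- generate_cohort(cs)
  rho <- cor(co$data$cd3_z, co$true_params$t1post_grf_clen_mm,
             method = "spearman")
  expect_equal(rho, 1)
})

test_that("the symmetric default link yields a balanced label fraction", {
  fracs <- vapply(1:5, function(s) {
    co <- generate_cohort(small_cohort_spec(n = 100, seed = s))
    mean(co$data$cd3_label == "high")
  }, 0.0)
  expect_true(all(fracs >= 0.3 & fracs <= 0.7))
})

test_that("cohort validation rejects undersized cohorts and bad links", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(cd3_link = list(coef = c(a = 1), noise_sd = -1)),
               "noise_sd")
})

test_that("NIfTI round trip preserves volumes, masks and spacing", {
  ph <- small_patient(2)
  d <- tempfile()
  dir.create(d)
  paths <- cd3radiomics:::write_phantom_patient(ph, d, "P001")
  pat <- read_patient(as.data.frame(paths))
  expect_equal(pat$t1post$values, ph$t1post$values, tolerance = 1e-6)
  expect_equal(pat$t1post$spacing, ph$t1post$spacing, tolerance = 1e-6)
  expect_identical(pat$tumor$mask, ph$tumor$mask)
  unlink(d, recursive = TRUE)
})

test_that("correlation length controls zone statistics monotonically across seeds", {
  # percolation regime at G = 8 / 26-connectivity: coarser fields raise
  # small-zone emphasis and NGTDM contrast and lower large-zone emphasis
  stats_at <- function(cl, s) {
    tp <- default_texture_params()
    tp$t1post$grf_clen_mm <- cl
    ph <- generate_phantom(small_phantom_spec(seed = s, texture_params = tp))
    prep <- preprocess_modality(ph$t1post, ph$tumor, ph$nawm)
    g <- glszm_features(prep$quantized)
    n <- ngtdm_features(prep$quantized)
    c(sze = g[["glszm_small_zone_emphasis"]],
      lze = g[["glszm_large_zone_emphasis"]],
      contrast = n[["ngtdm_contrast"]])
  }
  fine <- vapply(1:20, function(s) stats_at(2, s), numeric(3))
  coarse <- vapply(1:20, function(s) stats_at(5, s), numeric(3))
  expect_gt(mean(coarse["sze", ]), mean(fine["sze", ]))
  expect_lt(mean(coarse["lze", ]), mean(fine["lze", ]))
  expect_gt(mean(coarse["contrast", ]), mean(fine["contrast", ]))
})
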