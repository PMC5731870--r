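# Small shared fixtures for fast tests.

# compact phantom: ~1.6k tumor voxels, quick to generate and extract
small_phantom_spec <- function(seed = 1L, texture_params = default_texture_params()) {
  phantom_spec(grid_shape = c(40L, 40L, 14L), spacing_mm = c(0.9, 0.9, 3.0),
               tumor_center_mm = c(22, 22, 21), tumor_semiaxes_mm = c(10, 9, 8),
               nawm_center_mm = c(6, 6, 21), nawm_radius_mm = 4,
               texture_params = texture_params, seed = seed)
}

small_cohort_spec <- function(n = 12L, seed = 1L, ...) {
  cohort_spec(n_patients = n, seed = seed, grid_shape = c(40L, 40L, 14L), ...)
}

# patient record built from a small phantom, bypassing disk
small_patient <- function(seed = 1L) generate_phantom(small_phantom_spec(seed))

# constant-intensity volume with simple cubic tumor/nawm masks
toy_volume <- function(value = 100, dim = c(10L, 10L, 6L), spacing = c(1, 1, 1),
                       modality = "t1post") {
  volume_image(array(value, dim = dim), spacing, modality)
}

toy_masks <- function(dim = c(10L, 10L, 6L)) {
  tumor <- array(FALSE, dim = dim)
  tumor[3:7, 3:7, 2:5] <- TRUE
  nawm <- array(FALSE, dim = dim)
  nawm[9:10, 9:10, 2:5] <- TRUE
  list(tumor = roi_mask(tumor, "tumor"), nawm = roi_mask(nawm, "nawm"))
}
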