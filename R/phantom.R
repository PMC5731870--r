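#' Specification of one synthetic two-modality phantom
#'
#' Describes a 3D digital phantom emulating a contrast-enhancing brain tumor
#' imaged in two MRI modalities (T1 post-contrast, T2-FLAIR): an ellipsoidal
#' tumor and a spherical normal-appearing-white-matter (NAWM) reference region
#' on a common anisotropic grid. Tumor texture is a Gaussian random field
#' (white noise smoothed with a Gaussian kernel of the stated correlation
#' length) plus a radial rim-enhancement term and i.i.d. voxel noise, so
#' coarseness, contrast and heterogeneity are continuously and reproducibly
#' tunable.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3 voxel spacing in mm; anisotropic by
#'   default (0.9 x 0.9 x 3.0) so that isotropic reslicing is genuinely
#'   exercised.
#' @param tumor_center_mm,tumor_semiaxes_mm ellipsoid center and semi-axes in
#'   physical mm; semi-axes must be positive.
#' @param nawm_center_mm,nawm_radius_mm NAWM reference sphere (mm).
#' @param flair_margin scale factor (>= 1) applied to the tumor semi-axes for
#'   the FLAIR ROI, emulating the peritumoral edema margin segmented on
#'   FLAIR; the T1 ROI is the unscaled ellipsoid.
#' @param texture_params named list with entries `t1post` and `flair`, each a
#'   list with `base` (tumor base intensity), `grf_clen_mm` (random-field
#'   correlation length, mm), `grf_amp` (field amplitude), `rim_amp` and
#'   `rim_width_mm` (rim enhancement), `noise_sd` (additive voxel noise) and
#'   `nawm_base` (background/NAWM intensity).
#' @param seed integer; fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 20L),
                         spacing_mm = c(0.9, 0.9, 3.0),
                         tumor_center_mm = c(28.8, 28.8, 30),
                         tumor_semiaxes_mm = c(16, 14, 12),
                         nawm_center_mm = c(9, 9, 30),
                         nawm_radius_mm = 5,
                         flair_margin = 1.15,
                         texture_params = default_texture_params(),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("'grid_shape' must be 3 integers >= 2")
  if (any(spacing_mm <= 0)) stop("'spacing_mm' must be positive")
  if (any(tumor_semiaxes_mm <= 0)) stop("tumor semi-axes must be positive")
  if (nawm_radius_mm <= 0) stop("NAWM radius must be positive")
  if (flair_margin < 1) stop("'flair_margin' must be >= 1")
  for (mod in c("t1post", "flair")) {
    tp <- texture_params[[mod]]
    if (is.null(tp)) stop("texture_params must contain '", mod, "'")
    need <- c("base", "grf_clen_mm", "grf_amp", "rim_amp", "rim_width_mm",
              "noise_sd", "nawm_base")
    miss <- setdiff(need, names(tp))
    if (length(miss)) stop("texture_params$", mod, " missing: ",
                           paste(miss, collapse = ", "))
    if (tp$grf_clen_mm <= 0) stop("grf_clen_mm must be positive")
    if (tp$noise_sd < 0) stop("noise_sd must be >= 0")
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 tumor_center_mm = as.numeric(tumor_center_mm),
                 tumor_semiaxes_mm = as.numeric(tumor_semiaxes_mm),
                 nawm_center_mm = as.numeric(nawm_center_mm),
                 nawm_radius_mm = as.numeric(nawm_radius_mm),
                 flair_margin = as.numeric(flair_margin),
                 texture_params = texture_params, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-modality texture parameters
#'
#' T1 post-contrast gets a rim-enhancement term (contrast enhancement at the
#' tumor margin); FLAIR gets none but a coarser, stronger field (edema-like
#' diffuse hyperintensity).
#' @return Named list with `t1post` and `flair` parameter lists.
#' @export
default_texture_params <- function() {
  list(
    t1post = list(base = 300, grf_clen_mm = 3, grf_amp = 60,
                  rim_amp = 120, rim_width_mm = 3, noise_sd = 15,
                  nawm_base = 200),
    flair = list(base = 420, grf_clen_mm = 4, grf_amp = 80,
                 rim_amp = 0, rim_width_mm = 3, noise_sd = 20,
                 nawm_base = 250)
  )
}

gaussian_kernel_1d <- function(sd_vox) {
  r <- max(1L, as.integer(ceiling(3 * sd_vox)))
  k <- stats::dnorm(seq(-r, r), sd = sd_vox)
  k / sum(k)
}

# Smooth white noise into a unit-variance Gaussian random field with the
# requested physical correlation length; variance normalization uses the
# analytic L2 norm of the separable kernel.
gaussian_random_field <- function(dim, spacing, clen_mm) {
  white <- array(stats::rnorm(prod(dim)), dim = dim)
  ks <- lapply(1:3, function(a) gaussian_kernel_1d(clen_mm / spacing[a]))
  sm <- cpp_convolve_sep3(as.numeric(white), as.integer(dim),
                          ks[[1]], ks[[2]], ks[[3]])
  sd_theory <- prod(vapply(ks, function(k) sqrt(sum(k^2)), 0.0))
  array(sm / sd_theory, dim = dim)
}

voxel_center_grids <- function(dim, spacing) {
  list(x = (seq_len(dim[1]) - 0.5) * spacing[1],
       y = (seq_len(dim[2]) - 0.5) * spacing[2],
       z = (seq_len(dim[3]) - 0.5) * spacing[3])
}

#' Generate one phantom patient
#'
#' Renders both modality volumes, the tumor and NAWM masks, and returns the
#' true texture parameters. Intensities inside the tumor are
#' `base + grf_amp * field + rim + noise`; outside they are
#' `nawm_base + noise` (the textured random field is a tumor property; the
#' NAWM reference region stays flat so its mean is a stable, positive
#' normalization denominator). The rim term is
#' `rim_amp * exp(-d^2 / (2 * rim_width_mm^2))` with `d` the approximate
#' distance (mm) from the voxel to the ellipsoid surface, applied inside the
#' tumor only. All randomness is a pure function of `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return List with elements `t1post`, `flair` ([volume_image]s),
#'   `tumor_t1post`, `tumor_flair` (per-modality tumor [roi_mask]s; the FLAIR
#'   ROI is the `flair_margin`-scaled ellipsoid), `tumor` (alias for the T1
#'   mask), `nawm` and `true_params` (named numeric vector).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  g <- voxel_center_grids(d, spec$spacing_mm)
  ctr <- spec$tumor_center_mm
  ax <- spec$tumor_semiaxes_mm
  # ellipsoidal radial coordinate u (u <= 1 inside the tumor)
  u2 <- outer(outer(((g$x - ctr[1]) / ax[1])^2,
                    ((g$y - ctr[2]) / ax[2])^2, `+`),
              ((g$z - ctr[3]) / ax[3])^2, `+`)
  tumor <- u2 <= 1
  tumor_flair <- u2 <= spec$flair_margin^2
  nc <- spec$nawm_center_mm
  dist2 <- outer(outer((g$x - nc[1])^2, (g$y - nc[2])^2, `+`),
                 (g$z - nc[3])^2, `+`)
  nawm <- dist2 <= spec$nawm_radius_mm^2
  if (!any(tumor)) stop("tumor ellipsoid contains no voxels")
  if (!any(nawm)) stop("NAWM sphere contains no voxels")
  if (any(tumor_flair & nawm))
    stop("tumor and NAWM regions overlap (", sum(tumor_flair & nawm),
         " voxels); move them apart")

  # distance (mm) to the ellipsoid surface, approximated radially
  dist_boundary <- (sqrt(u2) - 1) * exp(mean(log(ax)))

  set.seed(spec$seed)
  vols <- list()
  for (mod in c("t1post", "flair")) {
    tp <- spec$texture_params[[mod]]
    region <- if (mod == "flair") tumor_flair else tumor
    field <- gaussian_random_field(d, spec$spacing_mm, tp$grf_clen_mm)
    vals <- array(tp$nawm_base, dim = d)
    vals[region] <- tp$base
    if (tp$rim_amp != 0) {
      rim <- tp$rim_amp * exp(-dist_boundary^2 / (2 * tp$rim_width_mm^2))
      vals[region] <- vals[region] + rim[region]
    }
    vals[region] <- vals[region] + tp$grf_amp * field[region]
    if (tp$noise_sd > 0)
      vals <- vals + array(stats::rnorm(prod(d), sd = tp$noise_sd), dim = d)
    vols[[mod]] <- volume_image(vals, spec$spacing_mm, mod)
  }

  tpv <- unlist(spec$texture_params)
  names(tpv) <- gsub("\\.", "_", names(tpv))
  tum_t1 <- roi_mask(tumor, "tumor")
  list(t1post = vols$t1post, flair = vols$flair,
       tumor = tum_t1, tumor_t1post = tum_t1,
       tumor_flair = roi_mask(tumor_flair, "tumor"),
       nawm = roi_mask(nawm, "nawm"),
       true_params = tpv)
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of phantom patients: per-patient texture parameters
#' drawn from uniform ranges, clinical covariates (age, sex, KPS) drawn
#' independently of CD3 (so covariate-adjustment analyses have a known null),
#' and a continuous CD3 z-score generated from known texture parameters via a
#' linear link plus Gaussian noise, dichotomized at 0 into high/low
#' infiltration.
#'
#' @param n_patients cohort size (>= 2).
#' @param param_ranges named list per modality of `c(lo, hi)` uniform ranges
#'   for texture parameters; parameters not listed stay at their
#'   [default_texture_params()] values.
#' @param cd3_link list with `coef` (named coefficients on standardized true
#'   parameters, names like `"t1post_grf_clen_mm"`) and `noise_sd` (>= 0).
#'   Parameters are standardized by the analytic mean and sd of their uniform
#'   range, so the deterministic part of the z-score has mean 0.
#' @param seed integer; fully determines the cohort.
#' @param grid_shape,spacing_mm forwarded to each patient's [phantom_spec].
#' @param size_scale_range per-patient uniform range for the isotropic tumor
#'   size factor (scales the default semi-axes, so volumes vary about
#'   two-fold), independent of CD3.
#' @param flair_margin_range per-patient uniform range for the FLAIR edema
#'   margin factor.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 150L,
                        param_ranges = default_param_ranges(),
                        cd3_link = default_cd3_link(),
                        seed = 1L,
                        grid_shape = c(64L, 64L, 20L),
                        spacing_mm = c(0.9, 0.9, 3.0),
                        size_scale_range = c(0.85, 1.1),
                        flair_margin_range = c(1.05, 1.25)) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("'n_patients' must be >= 2")
  if (is.null(cd3_link$noise_sd) || cd3_link$noise_sd < 0)
    stop("cd3_link$noise_sd must be >= 0")
  if (is.null(cd3_link$coef) || is.null(names(cd3_link$coef)))
    stop("cd3_link$coef must be a named numeric vector")
  if (size_scale_range[1] <= 0 || diff(size_scale_range) < 0)
    stop("'size_scale_range' must be an increasing positive range")
  structure(list(n_patients = n_patients, param_ranges = param_ranges,
                 cd3_link = cd3_link, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 size_scale_range = as.numeric(size_scale_range),
                 flair_margin_range = as.numeric(flair_margin_range)),
            class = "cohort_spec")
}

#' Default per-patient texture parameter ranges
#'
#' The T1 post-contrast correlation length spans fine to coarse texture
#' (1.5-6 mm); rim amplitude and field amplitude vary moderately so the
#' cohort is heterogeneous in contrast as well as coarseness.
#' @return Named list of uniform ranges per modality.
#' @export
default_param_ranges <- function() {
  list(
    t1post = list(grf_clen_mm = c(1.5, 6.0), grf_amp = c(40, 80),
                  rim_amp = c(80, 160)),
    flair = list(grf_clen_mm = c(2.0, 6.0), grf_amp = c(50, 90))
  )
}

#' Default texture-to-CD3 link
#'
#' CD3 z-score = standardized T1 post-contrast random-field correlation
#' length plus Gaussian noise (sd 0.45). Coarser T1 texture thus means higher
#' CD3 infiltration, and the signal-to-noise ratio leaves an appreciable but
#' imperfect ceiling on downstream classification (latent class-separation
#' AUC about 0.93), in line with a realistically noisy biomarker.
#' @return List with `coef` and `noise_sd`.
#' @export
default_cd3_link <- function() {
  list(coef = c(t1post_grf_clen_mm = 1.0), noise_sd = 0.45)
}

#' Image features that proxy the default CD3 link
#'
#' Under [default_cd3_link()] the CD3 score is driven by the T1 post-contrast
#' field correlation length, i.e. by texture coarseness. These are the
#' extracted features that measure that quantity most directly (size-zone
#' coarseness measures and the neighborhood coarseness/contrast statistics);
#' an all-relevant selector recovering the link is expected to confirm
#' features from this set.
#' @return Character vector of feature names.
#' @export
causal_feature_set <- function() {
  c("t1post_glszm_small_zone_emphasis",
    "t1post_glszm_large_zone_emphasis",
    "t1post_glszm_zone_percentage",
    "t1post_glszm_zone_size_nonuniformity",
    "t1post_ngtdm_coarseness",
    "t1post_ngtdm_contrast")
}

uniform_mean_sd <- function(rg) c(mean = mean(rg), sd = diff(rg) / sqrt(12))

#' Generate a synthetic cohort
#'
#' Draws per-patient texture parameters, covariates and CD3 outcomes, renders
#' every phantom, and (optionally) writes the cohort to disk as NIfTI volumes
#' plus a manifest CSV with columns `patient_id`, modality and mask paths,
#' `age`, `sex`, `kps`, `cd3_z`, `cd3_label`.
#'
#' @param cspec a [cohort_spec].
#' @param dir optional output directory; created if missing.
#' @param keep_volumes if `FALSE`, rendered volumes are dropped after writing
#'   (requires `dir`), keeping memory flat for large cohorts.
#' @return List with `patients` (list of [generate_phantom] outputs, or paths
#'   when `keep_volumes = FALSE`), `data` (data.frame of covariates and CD3),
#'   `true_params` (data.frame of per-patient linked parameters) and
#'   `manifest` (path, when written).
#' @export
generate_cohort <- function(cspec, dir = NULL, keep_volumes = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  if (!keep_volumes && is.null(dir))
    stop("'keep_volumes = FALSE' requires 'dir'")
  n <- cspec$n_patients
  set.seed(cspec$seed)

  # per-patient texture parameters
  draws <- list()
  for (mod in names(cspec$param_ranges))
    for (pn in names(cspec$param_ranges[[mod]])) {
      rg <- cspec$param_ranges[[mod]][[pn]]
      draws[[paste(mod, pn, sep = "_")]] <- stats::runif(n, rg[1], rg[2])
    }
  tp_df <- as.data.frame(draws)

  # covariates and tumor geometry, independent of CD3 by design
  age <- round(pmin(90, pmax(18, stats::rnorm(n, 58, 12))))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  kps <- sample(seq(60, 100, 10), n, replace = TRUE)
  size_scale <- stats::runif(n, cspec$size_scale_range[1],
                             cspec$size_scale_range[2])
  flair_margin <- stats::runif(n, cspec$flair_margin_range[1],
                               cspec$flair_margin_range[2])

  # CD3 link on standardized true parameters
  link <- cspec$cd3_link
  zdet <- numeric(n)
  for (nm in names(link$coef)) {
    if (is.null(tp_df[[nm]]))
      stop("cd3_link coefficient '", nm, "' has no drawn parameter")
    parts <- strsplit(nm, "_")[[1]]
    mod <- parts[1]
    pn <- paste(parts[-1], collapse = "_")
    ms <- uniform_mean_sd(cspec$param_ranges[[mod]][[pn]])
    zdet <- zdet + link$coef[[nm]] * (tp_df[[nm]] - ms["mean"]) / ms["sd"]
  }
  cd3_z <- zdet + stats::rnorm(n, 0, link$noise_sd)
  cd3_label <- ifelse(cd3_z > 0, "high", "low")

  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)

  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  patients <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tpar <- default_texture_params()
    for (mod in names(cspec$param_ranges))
      for (pn in names(cspec$param_ranges[[mod]]))
        tpar[[mod]][[pn]] <- tp_df[[paste(mod, pn, sep = "_")]][i]
    # geometry proportional to the physical grid extent, so any grid works
    extent <- cspec$grid_shape * cspec$spacing_mm
    ps <- phantom_spec(grid_shape = cspec$grid_shape,
                       spacing_mm = cspec$spacing_mm,
                       tumor_center_mm = extent / 2,
                       tumor_semiaxes_mm = size_scale[i] *
                         c(0.28 * extent[1], 0.245 * extent[2],
                           0.2 * extent[3]),
                       nawm_center_mm = c(0.16 * extent[1], 0.16 * extent[2],
                                          0.5 * extent[3]),
                       nawm_radius_mm = 0.087 * min(extent[1:2]),
                       flair_margin = flair_margin[i],
                       texture_params = tpar, seed = patient_seeds[i])
    ph <- generate_phantom(ps)
    pid <- sprintf("P%03d", i)
    row <- data.frame(patient_id = pid, age = age[i], sex = sex[i],
                      kps = kps[i], cd3_z = cd3_z[i],
                      cd3_label = cd3_label[i], stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      paths <- write_phantom_patient(ph, dir, pid)
      row <- cbind(row[, "patient_id", drop = FALSE], as.data.frame(paths),
                   row[, -1, drop = FALSE])
    }
    rows[[i]] <- row
    patients[[i]] <- if (keep_volumes) ph else NULL
  }
  data <- do.call(rbind, rows)
  manifest <- NULL
  if (!is.null(dir)) {
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(data, manifest, row.names = FALSE)
  }
  list(patients = patients, data = data,
       true_params = cbind(data.frame(patient_id = data$patient_id), tp_df),
       manifest = manifest)
}
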