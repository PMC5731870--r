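#' Reslice a volume (and its masks) to an isotropic grid
#'
#' Resamples intensities by trilinear interpolation and masks by
#' nearest-neighbor onto a grid with isotropic voxels of side `target_mm`.
#' Grids are half-voxel-centered (voxel i spans `[i, i+1] * spacing`, its
#' center at `(i + 0.5) * spacing`), so the physical extent is preserved
#' within one voxel. Multi-site MRI comes with anisotropic native spacing
#' (slice thickness often several times the in-plane resolution); texture
#' matrices assume comparable physical distance per voxel step, hence this
#' stage.
#'
#' @param vol a [volume_image].
#' @param masks a named or unnamed list of [roi_mask] objects on the same
#'   grid, or a single `roi_mask`, or `NULL`.
#' @param target_mm target isotropic voxel size in mm (default 1).
#' @return A list with elements `volume` (resliced [volume_image]) and
#'   `masks` (list of resliced [roi_mask], same names).
#' @export
reslice_isotropic <- function(vol, masks = NULL, target_mm = 1.0) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("'target_mm' must be a positive scalar")
  d <- dim(vol$values)
  if (any(d < 2L))
    stop("cannot reslice a degenerate volume: axis with a single slice ",
         "(dims ", paste(d, collapse = "x"), ")")
  single <- inherits(masks, "roi_mask")
  if (single) masks <- list(masks)
  if (!is.null(masks)) for (m in masks) check_same_grid(vol, m)

  odim <- pmax(1, round(d * vol$spacing / target_mm))
  vals <- cpp_reslice_trilinear(as.numeric(vol$values), as.integer(d),
                                vol$spacing, as.numeric(odim), target_mm)
  out_vol <- volume_image(array(vals, dim = odim),
                          rep(target_mm, 3), vol$modality)
  out_masks <- NULL
  if (!is.null(masks)) {
    out_masks <- lapply(masks, function(m) {
      mm <- cpp_reslice_nn(as.integer(m$mask), as.integer(d),
                           vol$spacing, as.numeric(odim), target_mm)
      roi_mask(array(mm == 1L, dim = odim), m$role)
    })
    names(out_masks) <- names(masks)
    if (single) out_masks <- out_masks[[1L]]
  }
  list(volume = out_vol, masks = out_masks)
}

#' Normalize intensities to the NAWM mean
#'
#' Divides every voxel by the mean intensity over the normal-appearing white
#' matter mask, so that tissue intensity becomes a unitless ratio relative to
#' contralateral white matter (NAWM mean of the output is exactly 1). This
#' removes the arbitrary scanner-dependent intensity scale of MRI.
#'
#' @param vol a [volume_image].
#' @param nawm the NAWM [roi_mask]; must be nonempty with strictly positive
#'   mean intensity.
#' @return The normalized [volume_image].
#' @export
normalize_to_nawm <- function(vol, nawm) {
  stopifnot(inherits(vol, "volume_image"), inherits(nawm, "roi_mask"))
  check_same_grid(vol, nawm)
  if (mask_count(nawm) == 0L) stop("NAWM mask is empty")
  m <- mean(vol$values[nawm$mask])
  if (!is.finite(m) || m <= 0)
    stop("NAWM mean intensity must be strictly positive (got ", format(m), ")")
  volume_image(vol$values / m, vol$spacing, vol$modality)
}

#' Quantize tumor intensities to G gray levels
#'
#' Equal-width binning over the in-mask intensity range:
#' `level = 1 + floor(G * (x - min) / (max - min))`, with `x = max` clamped to
#' level `G`. A constant ROI maps to level 1 everywhere. Equal-width binning
#' over the per-ROI min-max range is invariant to positive affine transforms
#' of the intensities.
#'
#' @param vol a [volume_image] (typically normalized and resliced).
#' @param tumor the tumor [roi_mask]; must be nonempty.
#' @param G number of gray levels (default 8).
#' @return A [quantized_roi].
#' @export
quantize <- function(vol, tumor, G = 8L) {
  stopifnot(inherits(vol, "volume_image"), inherits(tumor, "roi_mask"))
  check_same_grid(vol, tumor)
  if (mask_count(tumor) == 0L) stop("tumor mask is empty")
  G <- as.integer(G)
  if (G < 2L) stop("'G' must be >= 2")
  x <- vol$values[tumor$mask]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(vol$values))
  if (hi == lo) {
    lev[tumor$mask] <- 1L
  } else {
    q <- 1L + as.integer(floor(G * (x - lo) / (hi - lo)))
    q[q > G] <- G
    lev[tumor$mask] <- q
  }
  quantized_roi(lev, G, vol$spacing)
}

#' Preprocess one modality of a patient
#'
#' Runs the standard chain for a single modality: NAWM intensity
#' normalization, then isotropic reslicing of volume and masks, then
#' gray-level quantization of the tumor ROI. (Bias-field correction is an
#' upstream, external step: volumes are assumed shading-corrected on input.)
#'
#' @param vol a [volume_image].
#' @param tumor,nawm tumor and NAWM [roi_mask] objects on the volume's grid.
#' @param G gray levels for quantization.
#' @param target_mm isotropic voxel size in mm.
#' @return List with `volume` (normalized + resliced), `tumor`, `nawm`
#'   (resliced masks) and `quantized` (a [quantized_roi]).
#' @export
preprocess_modality <- function(vol, tumor, nawm, G = 8L, target_mm = 1.0) {
  nv <- normalize_to_nawm(vol, nawm)
  rs <- reslice_isotropic(nv, list(tumor = tumor, nawm = nawm), target_mm)
  if (mask_count(rs$masks$tumor) == 0L)
    stop("tumor mask became empty after reslicing")
  q <- quantize(rs$volume, rs$masks$tumor, G)
  list(volume = rs$volume, tumor = rs$masks$tumor, nawm = rs$masks$nawm,
       quantized = q)
}
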