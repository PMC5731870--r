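#' Construct a 3D scalar volume with physical spacing
#'
#' The basic imaging unit of the pipeline: a 3D array of intensities on a
#' regular grid with per-axis physical voxel spacing in millimetres and a
#' modality tag.
#'
#' @param values 3D numeric array of intensities (all finite).
#' @param spacing numeric length-3, voxel spacing in mm per axis (x, y, z);
#'   may be anisotropic, all entries must be positive.
#' @param modality one of `"t1post"` or `"flair"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing, modality = c("t1post", "flair")) {
  modality <- match.arg(tolower(modality), c("t1post", "flair"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)")
  structure(list(values = values, spacing = spacing, modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Construct a region-of-interest mask aligned to a volume
#'
#' @param mask 3D logical array on the same grid as its volume.
#' @param role `"tumor"` or `"nawm"` (normal-appearing white matter).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, role = c("tumor", "nawm")) {
  role <- match.arg(role)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(mask = mask, role = role), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> role=%s, %d voxels set of %d\n",
              x$role, sum(x$mask), length(x$mask)))
  invisible(x)
}

mask_count <- function(m) sum(m$mask)

check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$mask)))
    stop("mask grid (", paste(dim(mask$mask), collapse = "x"),
         ") does not match volume grid (",
         paste(dim(vol$values), collapse = "x"), ")")
  invisible(TRUE)
}

#' Quantized tumor region
#'
#' Integer gray levels 1..G at tumor voxels (0 outside the mask), carrying the
#' gray-level count and voxel spacing. Input to every texture matrix.
#'
#' @param levels 3D integer array, 0 outside the ROI, 1..G inside.
#' @param G number of gray levels (>= 2).
#' @param spacing voxel spacing in mm (length 3).
#' @return An object of class `quantized_roi`.
#' @export
quantized_roi <- function(levels, G, spacing) {
  if (!is.array(levels) || length(dim(levels)) != 3L)
    stop("'levels' must be a 3D array")
  storage.mode(levels) <- "integer"
  G <- as.integer(G)
  if (G < 2L) stop("'G' must be >= 2")
  inmask <- levels > 0L
  if (!any(inmask)) stop("quantized ROI is empty")
  if (any(levels[inmask] > G)) stop("levels exceed G")
  spacing <- as.numeric(spacing)
  structure(list(levels = levels, G = G, spacing = spacing,
                 mask = inmask, n_voxels = sum(inmask)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> G=%d, %d in-mask voxels\n", x$G, x$n_voxels))
  invisible(x)
}
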