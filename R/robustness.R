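#' The eight canonical ROI perturbations
#'
#' @return Character vector of perturbation kinds, in canonical order.
#' @export
perturbation_kinds <- function() {
  c("translate_h", "translate_hv", "rotate_1deg", "rotate_5deg",
    "jitter_sd0.1", "jitter_sd0.5", "dilate_1", "erode_1")
}

shift_mask <- function(m, dx = 0L, dy = 0L, dz = 0L) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  tx <- sx + dx; ty <- sy + dy; tz <- sz + dz
  okx <- tx >= 1 & tx <= d[1]; oky <- ty >= 1 & ty <= d[2]
  okz <- tz >= 1 & tz <= d[3]
  out[tx[okx], ty[oky], tz[okz]] <- m[sx[okx], sy[oky], sz[okz]]
  out
}

# 6-neighborhood (radius-1 ball) morphology via shifts
dilate6 <- function(m) {
  m | shift_mask(m, 1) | shift_mask(m, -1) |
    shift_mask(m, 0, 1) | shift_mask(m, 0, -1) |
    shift_mask(m, 0, 0, 1) | shift_mask(m, 0, 0, -1)
}
erode6 <- function(m) {
  m & shift_mask(m, 1) & shift_mask(m, -1) &
    shift_mask(m, 0, 1) & shift_mask(m, 0, -1) &
    shift_mask(m, 0, 0, 1) & shift_mask(m, 0, 0, -1)
}

rotate_mask_axial <- function(m, degrees) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  th <- degrees * pi / 180
  # inverse mapping: for each output in-plane voxel, sample the source voxel
  gx <- rep(seq_len(d[1]), times = d[2])
  gy <- rep(seq_len(d[2]), each = d[1])
  sx <- round(cx + cos(th) * (gx - cx) + sin(th) * (gy - cy))
  sy <- round(cy - sin(th) * (gx - cx) + cos(th) * (gy - cy))
  ok <- sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]
  out <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    slab <- m[, , z]
    o <- logical(d[1] * d[2])
    o[ok] <- slab[cbind(sx[ok], sy[ok])]
    out[, , z] <- o
  }
  out
}

jitter_mask <- function(m, sd, seed) {
  set.seed(seed)
  d <- dim(m)
  # in-plane boundary voxels: in mask with >= 1 out-of-mask 4-neighbor
  nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  inner <- m
  for (o in nb) inner <- inner & shift_mask(m, o[1], o[2])
  boundary <- which(m & !inner, arr.ind = TRUE)
  if (nrow(boundary) == 0L) return(m)
  # outward normal per boundary voxel: sum of offsets pointing out of mask
  normals <- matrix(0, nrow(boundary), 2)
  for (o in nb) {
    xx <- boundary[, 1] + o[1]; yy <- boundary[, 2] + o[2]
    inside <- xx >= 1 & xx <= d[1] & yy >= 1 & yy <= d[2]
    outp <- !inside
    outp[inside] <- !m[cbind(xx[inside], yy[inside], boundary[inside, 3])]
    normals[outp, 1] <- normals[outp, 1] + o[1]
    normals[outp, 2] <- normals[outp, 2] + o[2]
  }
  nrm <- sqrt(rowSums(normals^2))
  nrm[nrm == 0] <- 1
  # the true contour sits at a uniform sub-voxel offset within its boundary
  # voxel; displacing it by N(0, sd) and re-rasterizing rounds the sum, so
  # even sd = 0.1 flips the occasional near-edge voxel
  disp <- stats::rnorm(nrow(boundary), 0, sd) +
    stats::runif(nrow(boundary), -0.5, 0.5)
  out <- m
  grow <- disp >= 0.5
  shrink <- disp <= -0.5
  if (any(grow)) {
    step <- round(normals[grow, , drop = FALSE] / nrm[grow])
    gx <- boundary[grow, 1] + step[, 1]
    gy <- boundary[grow, 2] + step[, 2]
    okg <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2]
    out[cbind(gx[okg], gy[okg], boundary[grow, 3][okg])] <- TRUE
  }
  if (any(shrink))
    out[boundary[shrink, , drop = FALSE]] <- FALSE
  out
}

#' Apply one geometric perturbation to an ROI mask
#'
#' The eight canonical kinds, interpreted on the (post-reslicing, 1 mm) voxel
#' grid: in-plane translation by 2 voxels (horizontal; horizontal +
#' vertical), axial-plane rotation by 1 or 5 degrees about the mask centroid
#' with nearest-neighbor resampling, random boundary jitter (each in-plane
#' boundary voxel displaced along its local outward normal by a zero-mean
#' Gaussian of sd 0.1 or 0.5 voxels, re-rasterized), and radial
#' dilation/erosion by a 1-voxel ball.
#'
#' @param mask a [roi_mask] (nonempty).
#' @param kind one of [perturbation_kinds()].
#' @param seed integer seed; required for the jitter kinds.
#' @return The perturbed [roi_mask].
#' @export
perturb_mask <- function(mask, kind, seed = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  kind <- match.arg(kind, perturbation_kinds())
  if (mask_count(mask) == 0L) stop("mask is empty")
  m <- mask$mask
  out <- switch(kind,
    translate_h = shift_mask(m, 2L),
    translate_hv = shift_mask(m, 2L, 2L),
    rotate_1deg = rotate_mask_axial(m, 1),
    rotate_5deg = rotate_mask_axial(m, 5),
    "jitter_sd0.1" = {
      if (is.null(seed)) stop("jitter perturbations require a seed")
      jitter_mask(m, 0.1, seed)
    },
    "jitter_sd0.5" = {
      if (is.null(seed)) stop("jitter perturbations require a seed")
      jitter_mask(m, 0.5, seed)
    },
    dilate_1 = dilate6(m),
    erode_1 = erode6(m))
  if (!any(out))
    stop("perturbation '", kind, "' emptied the mask")
  roi_mask(out, mask$role)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA of a
#' subjects-by-versions matrix with `k` versions per subject. When the total
#' variance is zero (identical measurements), ICC is defined as 1 and the
#' `degenerate` attribute is set. `type = "ICC3"` gives the two-way mixed,
#' consistency form ICC(3,1) instead.
#'
#' @param values numeric matrix, subjects in rows, versions in columns; at
#'   least 2 of each, all finite.
#' @param type `"ICC1"` (default) or `"ICC3"`.
#' @return ICC estimate in `[-1, 1]`.
#' @export
icc <- function(values, type = c("ICC1", "ICC3")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 versions")
  if (!all(is.finite(values))) stop("ICC input must be finite")
  if (stats::var(as.numeric(values)) == 0)
    return(structure(1, degenerate = TRUE))
  rowm <- rowMeans(values)
  grand <- mean(values)
  ssb <- k * sum((rowm - grand)^2)
  msb <- ssb / (n - 1)
  if (type == "ICC1") {
    ssw <- sum((values - rowm)^2)
    msw <- ssw / (n * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    colm <- colMeans(values)
    ssc <- n * sum((colm - grand)^2)
    sse <- sum((sweep(sweep(values, 1, rowm), 2, colm) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msb - mse) / (msb + (k - 1) * mse)
  }
}

#' Screen features for robustness to ROI perturbation
#'
#' Given feature tables for the original ROI and each perturbed version,
#' computes the per-feature ICC across the 9 versions and retains features
#' with `ICC >= threshold`. Negative ICC estimates are clamped to 0 in the
#' report (flagged in the `clamped` column); the retention decision uses the
#' clamped value.
#'
#' @param feature_versions list of 9 data.frames/matrices (original first,
#'   then the 8 perturbations), identical patients-by-features layout.
#' @param threshold ICC retention threshold (default 0.6).
#' @param type forwarded to [icc()].
#' @return List with `retained` (character vector) and `report` (data.frame
#'   `feature`, `icc`, `icc_raw`, `clamped`, `pass`, `threshold`,
#'   `n_subjects`, `n_versions`).
#' @export
robust_features <- function(feature_versions, threshold = 0.6,
                            type = "ICC1") {
  k <- length(feature_versions)
  if (k < 2L) stop("need at least 2 feature versions")
  mats <- lapply(feature_versions, function(x) {
    x <- as.data.frame(x)
    x <- x[, setdiff(colnames(x), "patient_id"), drop = FALSE]
    as.matrix(x)
  })
  cn <- colnames(mats[[1]])
  dims <- vapply(mats, function(m) all(dim(m) == dim(mats[[1]])), TRUE)
  if (!all(dims)) stop("feature versions have inconsistent dimensions")
  raw <- vapply(cn, function(f) {
    icc(vapply(mats, function(m) m[, f], numeric(nrow(mats[[1]]))), type)
  }, 0.0)
  clamped <- pmax(raw, 0)
  report <- data.frame(feature = cn, icc = clamped, icc_raw = raw,
                       clamped = raw < 0, pass = clamped >= threshold,
                       threshold = threshold,
                       n_subjects = nrow(mats[[1]]), n_versions = k,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = cn[report$pass], report = report)
}

#' Full robustness assessment of a cohort
#'
#' For every patient and modality, preprocesses once, then re-extracts the
#' 43-feature modality panel under the original tumor ROI and each of the 8
#' perturbed versions (perturbations act on the resliced 1 mm mask; the
#' normalized, resliced volume is fixed). Feature robustness is assessed per
#' modality: a feature must be stable in its own modality only.
#'
#' @param patients list of patient records (as from [generate_cohort()]).
#' @param G,target_mm preprocessing parameters.
#' @param threshold ICC retention threshold (default 0.6).
#' @param seed seed for the jitter perturbations (recorded in the report).
#' @return As [robust_features()], over all 86 features, plus `seed`.
#' @export
assess_robustness <- function(patients, G = 8L, target_mm = 1.0,
                              threshold = 0.6, seed = 1L) {
  kinds <- perturbation_kinds()
  versions <- vector("list", length(kinds) + 1L)
  for (v in seq_along(versions)) versions[[v]] <- list()
  for (p in seq_along(patients)) {
    pat <- patients[[p]]
    row <- numeric(0)
    rows_pert <- vector("list", length(kinds))
    for (mod in c("t1post", "flair")) {
      tumor <- if (!is.null(pat[[paste0("tumor_", mod)]]))
        pat[[paste0("tumor_", mod)]] else pat[["tumor"]]
      nawm <- if (!is.null(pat[[paste0("nawm_", mod)]]))
        pat[[paste0("nawm_", mod)]] else pat[["nawm"]]
      prep <- preprocess_modality(pat[[mod]], tumor, nawm, G, target_mm)
      f0 <- modality_features(prep)
      names(f0) <- paste(mod, names(f0), sep = "_")
      row <- c(row, f0)
      for (ki in seq_along(kinds)) {
        pm <- perturb_mask(prep$tumor, kinds[ki],
                           seed = seed + 1000L * p + ki)
        qz <- quantize(prep$volume, pm, G)
        fk <- c(histogram_features(qz), gtsdm_features(qz),
                ngtdm_features(qz), glszm_features(qz),
                regional_features(prep$volume, pm))
        names(fk) <- paste(mod, names(fk), sep = "_")
        rows_pert[[ki]] <- c(rows_pert[[ki]], fk)
      }
    }
    versions[[1]][[p]] <- row
    for (ki in seq_along(kinds))
      versions[[ki + 1L]][[p]] <- rows_pert[[ki]]
  }
  tables <- lapply(versions, function(v) do.call(rbind, v))
  out <- robust_features(tables, threshold)
  out$seed <- seed
  out
}
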