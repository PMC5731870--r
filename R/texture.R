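#' Histogram features of a quantized ROI
#'
#' First-order statistics of the in-mask gray levels: mean, variance,
#' skewness, kurtosis, entropy and uniformity. Moments are population moments
#' (`m_k = mean((x - mean)^k)`); skewness is `m3 / m2^1.5`; kurtosis is the
#' Pearson (non-excess) convention `m4 / m2^2`, so a normal distribution has
#' kurtosis 3. Entropy is `-sum(p * log2(p))` over level probabilities and
#' uniformity (energy) is `sum(p^2)`. A zero-variance ROI reports skewness and
#' kurtosis 0 and sets the `degenerate` attribute.
#'
#' @param q a [quantized_roi].
#' @return Named numeric vector of 6 features (`hist_*`).
#' @export
histogram_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  x <- as.numeric(q$levels[q$mask])
  m <- mean(x)
  m2 <- mean((x - m)^2)
  degenerate <- m2 == 0
  skew <- if (degenerate) 0 else mean((x - m)^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean((x - m)^4) / m2^2
  p <- tabulate(q$levels[q$mask], nbins = q$G) / length(x)
  pp <- p[p > 0]
  out <- c(hist_mean = m, hist_variance = m2, hist_skewness = skew,
           hist_kurtosis = kurt, hist_entropy = -sum(pp * log2(pp)),
           hist_uniformity = sum(p^2))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Gray-level co-occurrence (GTSDM) features
#'
#' Builds a single gray-level co-occurrence matrix over the 13 unique 3D
#' unit-offset directions at distance 1, counting only voxel pairs with both
#' ends inside the mask, accumulated symmetrically and pooled (summed) across
#' directions before normalization to probabilities. Returns the 13 Haralick
#' features plus autocorrelation, cluster shade/prominence/tendency,
#' dissimilarity and maximum probability (19 in all).
#'
#' Degenerate guards: with a single occupied gray level, correlation is
#' reported as 1 and the information measures of correlation as 0, with the
#' `degenerate` attribute set.
#'
#' @param q a [quantized_roi].
#' @return Named numeric vector of 19 features (`glcm_*`).
#' @export
gtsdm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  counts <- cpp_glcm(as.integer(q$levels), as.integer(dim(q$levels)), q$G)
  tot <- sum(counts)
  if (tot == 0) stop("ROI has no valid voxel pairs for co-occurrence")
  P <- counts / tot
  G <- q$G
  i <- row(P); j <- col(P)
  px <- rowSums(P)                    # == colSums by symmetry
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  degenerate <- sig2 == 0

  # p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), 0.0)
  pdiff <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), 0.0)
  ks <- 2:(2 * G)
  kd <- 0:(G - 1)
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (degenerate) 1 else
    sum((i - mu) * (j - mu) * P) / sig2
  sos_variance <- sum((i - mu)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- ent0(psum)
  entropy <- ent0(P)
  diff_average <- sum(kd * pdiff)
  diff_variance <- sum((kd - diff_average)^2 * pdiff)
  diff_entropy <- ent0(pdiff)
  # information measures of correlation
  hx <- ent0(px)
  pxy <- outer(px, px)
  nz <- P > 0 & pxy > 0
  hxy1 <- -sum(P[nz] * log2(pxy[nz]))
  hxy2 <- ent0(pxy)
  imc1 <- if (hx == 0) 0 else (entropy - hxy1) / hx
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - entropy))))
  autocorrelation <- sum(i * j * P)
  cs <- i + j - 2 * mu
  cluster_shade <- sum(cs^3 * P)
  cluster_prominence <- sum(cs^4 * P)
  cluster_tendency <- sum(cs^2 * P)
  dissimilarity <- sum(abs(i - j) * P)
  max_probability <- max(P)

  out <- c(glcm_energy = energy, glcm_contrast = contrast,
           glcm_correlation = correlation, glcm_sum_of_squares = sos_variance,
           glcm_homogeneity = homogeneity, glcm_sum_average = sum_average,
           glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
           glcm_entropy = entropy, glcm_difference_variance = diff_variance,
           glcm_difference_entropy = diff_entropy, glcm_imc1 = imc1,
           glcm_imc2 = imc2, glcm_autocorrelation = autocorrelation,
           glcm_cluster_shade = cluster_shade,
           glcm_cluster_prominence = cluster_prominence,
           glcm_cluster_tendency = cluster_tendency,
           glcm_dissimilarity = dissimilarity,
           glcm_max_probability = max_probability)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

# Large sentinel for coarseness of a perfectly uniform region (the
# Amadasun-King denominator is 0 there). Documented and constant.
NGTDM_COARSENESS_CAP <- 1e6

#' Neighborhood gray-tone difference (NGTDM) features
#'
#' For each in-mask voxel with at least one in-mask 26-neighbor, the absolute
#' deviation of its level from the mean level of those neighbors is
#' accumulated per gray level (`s_i`), alongside occurrence probabilities
#' `p_i` over the `N` contributing voxels. The five Amadasun-King features
#' follow:
#' \itemize{
#' \item coarseness `1 / sum(p_i s_i)` (capped at 1e6 when the sum is 0);
#' \item contrast `[1/(Ngp (Ngp-1)) sum_ij p_i p_j (i-j)^2] * [sum(s_i) / N]`
#'   (0 when only one level occurs);
#' \item busyness `sum(p_i s_i) / sum_ij |i p_i - j p_j|` over occupied
#'   levels (0 when the denominator is 0);
#' \item complexity `(1/N) sum_ij |i-j| (p_i s_i + p_j s_j)/(p_i + p_j)`;
#' \item strength `sum_ij (p_i + p_j)(i-j)^2 / sum(s_i)` (0 when all `s_i`
#'   are 0).
#' }
#'
#' @param q a [quantized_roi].
#' @return Named numeric vector of 5 features (`ngtdm_*`).
#' @export
ngtdm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  tab <- cpp_ngtdm(as.integer(q$levels), as.integer(dim(q$levels)), q$G)
  n_i <- tab$n
  s_i <- tab$s
  N <- sum(n_i)
  if (N == 0) stop("all ROI voxels are isolated; NGTDM undefined")
  p_i <- n_i / N
  occ <- which(p_i > 0)
  Ngp <- length(occ)

  ps <- sum(p_i * s_i)
  coarseness <- if (ps == 0) NGTDM_COARSENESS_CAP else min(1 / ps, NGTDM_COARSENESS_CAP)

  contrast <- if (Ngp <= 1) 0 else {
    term1 <- 0
    for (a in occ) for (b in occ)
      term1 <- term1 + p_i[a] * p_i[b] * (a - b)^2
    term1 / (Ngp * (Ngp - 1)) * sum(s_i) / N
  }

  busy_den <- 0
  complexity <- 0
  strength_num <- 0
  for (a in occ) for (b in occ) {
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    complexity <- complexity +
      abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
  }
  busyness <- if (busy_den == 0) 0 else ps / busy_den
  complexity <- complexity / N
  strength <- if (sum(s_i) == 0) 0 else strength_num / sum(s_i)

  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are maximal 26-connected components of equal gray level; the matrix
#' entry `P(i, j)` counts zones of level `i` and size `j` voxels. With
#' `Nz = sum(P)` zones and `Np` in-mask voxels, the 11 features are the usual
#' size/gray-level emphases, non-uniformities and zone percentage `Nz / Np`.
#' Zone sizes always satisfy the conservation `sum_ij j P(i,j) = Np`.
#'
#' @param q a [quantized_roi].
#' @return Named numeric vector of 11 features (`glszm_*`).
#' @export
glszm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  z <- cpp_glszm_zones(as.integer(q$levels), as.integer(dim(q$levels)))
  glszm_features_from_zones(z$level, z$size, q$n_voxels)
}

glszm_features_from_zones <- function(level, size, n_voxels) {
  nz <- length(size)
  i <- as.numeric(level)
  j <- as.numeric(size)
  gln <- sum(tapply(rep(1, nz), i, sum)^2) / nz
  zsn <- sum(tapply(rep(1, nz), j, sum)^2) / nz
  c(glszm_small_zone_emphasis = sum(1 / j^2) / nz,
    glszm_large_zone_emphasis = sum(j^2) / nz,
    glszm_gray_level_nonuniformity = gln,
    glszm_zone_size_nonuniformity = zsn,
    glszm_zone_percentage = nz / n_voxels,
    glszm_low_gray_zone_emphasis = sum(1 / i^2) / nz,
    glszm_high_gray_zone_emphasis = sum(i^2) / nz,
    glszm_small_zone_low_gray_emphasis = sum(1 / (i^2 * j^2)) / nz,
    glszm_small_zone_high_gray_emphasis = sum(i^2 / j^2) / nz,
    glszm_large_zone_low_gray_emphasis = sum(j^2 / i^2) / nz,
    glszm_large_zone_high_gray_emphasis = sum(i^2 * j^2) / nz)
}

#' Regional (volumetric) features
#'
#' Tumor volume in mm^3 (voxel count times voxel volume) and the sum of
#' normalized intensities over the tumor mask.
#'
#' @param vol_normalized a NAWM-normalized [volume_image].
#' @param tumor the tumor [roi_mask].
#' @return Named numeric vector of 2 features (`regional_*`).
#' @export
regional_features <- function(vol_normalized, tumor) {
  stopifnot(inherits(vol_normalized, "volume_image"),
            inherits(tumor, "roi_mask"))
  check_same_grid(vol_normalized, tumor)
  if (mask_count(tumor) == 0L) stop("tumor mask is empty")
  c(regional_volume_mm3 = sum(tumor$mask) * prod(vol_normalized$spacing),
    regional_total_intensity = sum(vol_normalized$values[tumor$mask]))
}

#' All 43 features of one preprocessed modality
#'
#' 6 histogram + 19 co-occurrence + 5 NGTDM + 11 GLSZM texture features of
#' the quantized tumor ROI, plus the 2 regional features of the normalized
#' volume.
#'
#' @param prep output of [preprocess_modality()].
#' @return Named numeric vector of 43 features (unprefixed).
#' @export
modality_features <- function(prep) {
  q <- prep$quantized
  c(histogram_features(q), gtsdm_features(q), ngtdm_features(q),
    glszm_features(q), regional_features(prep$volume, prep$tumor))
}

#' Extract the full 86-feature panel for one patient
#'
#' Preprocesses each modality (NAWM normalization, isotropic reslicing,
#' quantization to `G` levels) and extracts 43 features per modality,
#' concatenated as `t1post_*` then `flair_*` in a fixed order (86 features,
#' all finite).
#'
#' @param patient list with `t1post` and `flair` [volume_image]s and `tumor`,
#'   `nawm` [roi_mask]s (per-modality masks may be supplied as
#'   `tumor_t1post`, `nawm_flair`, etc.; the shared `tumor`/`nawm` masks are
#'   the fallback).
#' @param G gray levels (default 8).
#' @param target_mm isotropic voxel size (default 1 mm).
#' @return Named numeric vector of 86 features.
#' @export
extract_all <- function(patient, G = 8L, target_mm = 1.0) {
  out <- numeric(0)
  for (mod in c("t1post", "flair")) {
    vol <- patient[[mod]]
    if (is.null(vol)) stop("patient record is missing modality '", mod, "'")
    tumor <- patient[[paste0("tumor_", mod)]]
    if (is.null(tumor)) tumor <- patient[["tumor"]]
    nawm <- patient[[paste0("nawm_", mod)]]
    if (is.null(nawm)) nawm <- patient[["nawm"]]
    if (is.null(tumor) || is.null(nawm))
      stop("patient record is missing tumor/NAWM masks for '", mod, "'")
    prep <- preprocess_modality(vol, tumor, nawm, G, target_mm)
    f <- modality_features(prep)
    names(f) <- paste(mod, names(f), sep = "_")
    out <- c(out, f)
  }
  if (!all(is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' The canonical 86-feature name registry
#'
#' Fixed ordering: per modality (t1post, flair) the 6 histogram, 19
#' co-occurrence, 5 NGTDM, 11 GLSZM and 2 regional features.
#' @return Character vector of length 86.
#' @export
feature_names <- function() {
  base <- c(
    paste0("hist_", c("mean", "variance", "skewness", "kurtosis", "entropy",
                      "uniformity")),
    paste0("glcm_", c("energy", "contrast", "correlation", "sum_of_squares",
                      "homogeneity", "sum_average", "sum_variance",
                      "sum_entropy", "entropy", "difference_variance",
                      "difference_entropy", "imc1", "imc2", "autocorrelation",
                      "cluster_shade", "cluster_prominence",
                      "cluster_tendency", "dissimilarity",
                      "max_probability")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")),
    paste0("glszm_", c("small_zone_emphasis", "large_zone_emphasis",
                       "gray_level_nonuniformity", "zone_size_nonuniformity",
                       "zone_percentage", "low_gray_zone_emphasis",
                       "high_gray_zone_emphasis",
                       "small_zone_low_gray_emphasis",
                       "small_zone_high_gray_emphasis",
                       "large_zone_low_gray_emphasis",
                       "large_zone_high_gray_emphasis")),
    paste0("regional_", c("volume_mm3", "total_intensity")))
  c(paste0("t1post_", base), paste0("flair_", base))
}

#' Extract features for a whole cohort
#'
#' @param cohort output of [generate_cohort()] (with volumes kept), or a list
#'   of patient records plus a data.frame.
#' @param G,target_mm forwarded to [extract_all()].
#' @return data.frame with `patient_id` and the 86 feature columns.
#' @export
extract_cohort <- function(cohort, G = 8L, target_mm = 1.0) {
  pats <- cohort$patients
  ids <- cohort$data$patient_id
  feats <- vapply(pats, extract_all, numeric(86L), G = G,
                  target_mm = target_mm)
  out <- as.data.frame(t(feats))
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), out)
}
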