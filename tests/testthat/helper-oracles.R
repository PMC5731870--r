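# Independent brute-force oracles for the texture matrices: naive R
# enumeration of voxel pairs, neighborhoods and zones, written directly from
# the definitions and kept free of any package kernel.

# build a quantized_roi from a 3D integer array (0 = outside mask)
qroi <- function(arr, G = max(arr), spacing = c(1, 1, 1)) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  if (length(dim(arr)) != 3) arr <- array(arr, dim = c(length(arr), 1, 1))
  quantized_roi(arr, G = max(2L, G), spacing = spacing)
}

offsets13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

in_grid <- function(v, d) all(v >= 1) && all(v <= d)

oracle_glcm <- function(lev, G) {
  d <- dim(lev)
  M <- matrix(0, G, G)
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (o in seq_len(nrow(offsets13))) {
      w <- v + offsets13[o, ]
      if (!in_grid(w, d)) next
      l2 <- lev[w[1], w[2], w[3]]
      if (l2 <= 0) next
      l1 <- lev[v[1], v[2], v[3]]
      M[l1, l2] <- M[l1, l2] + 1
      M[l2, l1] <- M[l2, l1] + 1
    }
  }
  M
}

oracle_glcm_features <- function(lev, G) {
  M <- oracle_glcm(lev, G)
  stopifnot(sum(M) > 0)
  P <- M / sum(M)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  psum <- sapply(2:(2 * G), function(k) sum(P[i + j == k]))
  pdiff <- sapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]))
  ks <- 2:(2 * G); kd <- 0:(G - 1)
  sa <- sum(ks * psum)
  da <- sum(kd * pdiff)
  hx <- ent0(px)
  hxy <- ent0(P)
  pxy <- outer(px, px)
  nz <- P > 0 & pxy > 0
  hxy1 <- -sum(P[nz] * log2(pxy[nz]))
  hxy2 <- ent0(pxy)
  c(glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = if (sig2 == 0) 1 else sum((i - mu) * (j - mu) * P) / sig2,
    glcm_sum_of_squares = sum((i - mu)^2 * P),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ks - sa)^2 * psum),
    glcm_sum_entropy = ent0(psum),
    glcm_entropy = hxy,
    glcm_difference_variance = sum((kd - da)^2 * pdiff),
    glcm_difference_entropy = ent0(pdiff),
    glcm_imc1 = if (hx == 0) 0 else (hxy - hxy1) / hx,
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy)))),
    glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_max_probability = max(P))
}

oracle_ngtdm <- function(lev, G) {
  d <- dim(lev)
  n_i <- numeric(G); s_i <- numeric(G)
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    nb <- c()
    for (o in seq_len(nrow(offsets26))) {
      w <- v + offsets26[o, ]
      if (!in_grid(w, d)) next
      l2 <- lev[w[1], w[2], w[3]]
      if (l2 > 0) nb <- c(nb, l2)
    }
    if (length(nb) > 0) {
      l <- lev[v[1], v[2], v[3]]
      n_i[l] <- n_i[l] + 1
      s_i[l] <- s_i[l] + abs(l - mean(nb))
    }
  }
  list(n = n_i, s = s_i)
}

oracle_ngtdm_features <- function(lev, G) {
  tab <- oracle_ngtdm(lev, G)
  N <- sum(tab$n)
  stopifnot(N > 0)
  p <- tab$n / N
  s <- tab$s
  occ <- which(p > 0)
  Ngp <- length(occ)
  ps <- sum(p * s)
  coarseness <- if (ps == 0) 1e6 else min(1 / ps, 1e6)
  contrast <- if (Ngp <= 1) 0 else {
    t1 <- sum(outer(p[occ], p[occ]) * outer(occ, occ, function(a, b) (a - b)^2))
    t1 / (Ngp * (Ngp - 1)) * sum(s) / N
  }
  bd <- sum(abs(outer(occ * p[occ], occ * p[occ], `-`)))
  busyness <- if (bd == 0) 0 else ps / bd
  cx <- 0; st <- 0
  for (a in occ) for (b in occ) {
    cx <- cx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    st <- st + (p[a] + p[b]) * (a - b)^2
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = cx / N,
    ngtdm_strength = if (sum(s) == 0) 0 else st / sum(s))
}

# flood-fill zones with 26-connectivity, naive R implementation
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  idx <- which(lev > 0)
  for (start in idx) {
    if (seen[start]) next
    lv <- lev[start]
    stack <- start
    seen[start] <- TRUE
    members <- c()
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      members <- c(members, cur)
      v <- arrayInd(cur, d)
      for (o in seq_len(nrow(offsets26))) {
        w <- as.integer(v) + offsets26[o, ]
        if (!in_grid(w, d)) next
        li <- w[1] + d[1] * ((w[2] - 1) + d[2] * (w[3] - 1))
        if (!seen[li] && lev[li] == lv) {
          seen[li] <- TRUE
          stack <- c(stack, li)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lv, size = length(members))
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lev) {
  z <- oracle_zones(lev)
  np <- sum(lev > 0)
  nz <- nrow(z)
  i <- z[, "level"]; j <- z[, "size"]
  c(glszm_small_zone_emphasis = sum(1 / j^2) / nz,
    glszm_large_zone_emphasis = sum(j^2) / nz,
    glszm_gray_level_nonuniformity = sum(table(i)^2) / nz,
    glszm_zone_size_nonuniformity = sum(table(j)^2) / nz,
    glszm_zone_percentage = nz / np,
    glszm_low_gray_zone_emphasis = sum(1 / i^2) / nz,
    glszm_high_gray_zone_emphasis = sum(i^2) / nz,
    glszm_small_zone_low_gray_emphasis = sum(1 / (i^2 * j^2)) / nz,
    glszm_small_zone_high_gray_emphasis = sum(i^2 / j^2) / nz,
    glszm_large_zone_low_gray_emphasis = sum(j^2 / i^2) / nz,
    glszm_large_zone_high_gray_emphasis = sum(i^2 * j^2) / nz)
}

# random quantized array with a random mask, for oracle fuzzing
random_quantized <- function(seed, max_side = 5, G = 4) {
  set.seed(seed)
  d <- sample(2:max_side, 3, replace = TRUE)
  lev <- array(sample.int(G, prod(d), replace = TRUE), dim = d)
  mask <- array(runif(prod(d)) < 0.8, dim = d)
  if (!any(mask)) mask[1] <- TRUE
  lev[!mask] <- 0L
  lev
}
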