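#' All-relevant feature selection against a continuous outcome
#'
#' Shadow-feature (Boruta-style) selection: each round appends a freshly
#' permuted shadow copy of every feature, fits a random-forest regressor
#' (z-scored permutation importance, via ranger), and scores a "hit" for
#' every undecided feature whose importance exceeds the maximum shadow
#' importance. Accumulated hit counts are tested against the binomial(rounds,
#' 1/2) null with a two-sided test at level `alpha`, Bonferroni-corrected for
#' the number of input features: significantly more hits than chance confirms
#' a feature, significantly fewer rejects it. All features and all shadows
#' stay in the forest every round, so the shadow reference always reflects
#' the full panel's spurious-correlation spectrum. Features still undecided
#' after `max_rounds` are tentative and are resolved by comparing their
#' median importance across rounds with the median of the max-shadow
#' importances.
#'
#' Unlike minimal-subset selectors, this keeps every feature carrying signal,
#' including correlated duplicates — the all-relevant property.
#'
#' @param X data.frame or matrix of features (no missing values, >= 10 rows);
#'   a `patient_id` column is ignored.
#' @param y continuous outcome (e.g. CD3 z-scores); must not be constant.
#' @param max_rounds maximum number of rounds (default 100).
#' @param seed integer seed (drives permutations and forests).
#' @param alpha test level before Bonferroni correction (default 0.01).
#' @param num_trees trees per forest (default 500).
#' @return Object of class `boruta_result`: list with `confirmed`,
#'   `tentative` (as finally resolved: empty unless resolution was
#'   impossible), `rejected`, `tentative_resolved` (data.frame),
#'   `importance_history` (rounds x features, NA once decided),
#'   `shadow_max_history`, `rounds`, `seed`.
#' @export
boruta_select <- function(X, y, max_rounds = 100L, seed = 1L, alpha = 0.01,
                          num_trees = 500L) {
  X <- as.data.frame(X)
  X$patient_id <- NULL
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) < 10L) stop("need at least 10 samples")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (stats::var(y) == 0) stop("outcome 'y' is constant")
  feats <- colnames(X)
  m <- length(feats)
  alpha_bonf <- alpha / m

  set.seed(seed)
  status <- stats::setNames(rep("undecided", m), feats)
  hits <- stats::setNames(rep(0L, m), feats)
  tested <- stats::setNames(rep(0L, m), feats)
  imp_hist <- matrix(NA_real_, nrow = max_rounds, ncol = m,
                     dimnames = list(NULL, feats))
  shadow_hist <- rep(NA_real_, max_rounds)

  r <- 0L
  while (r < max_rounds && any(status == "undecided")) {
    r <- r + 1L
    undecided <- feats[status == "undecided"]
    sh <- as.data.frame(lapply(X, sample))
    colnames(sh) <- paste0(".shadow.", colnames(sh))
    df <- cbind(X, sh, .outcome = y)
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = df,
      num.trees = num_trees, importance = "permutation",
      scale.permutation.importance = TRUE,
      seed = seed + r, num.threads = 1L, respect.unordered.factors = TRUE)
    imp <- fit$variable.importance
    shadow_max <- max(imp[grepl("^\\.shadow\\.", names(imp))])
    shadow_hist[r] <- shadow_max
    imp_hist[r, feats] <- imp[feats]
    hit <- imp[undecided] > shadow_max
    hits[undecided] <- hits[undecided] + as.integer(hit)
    tested[undecided] <- tested[undecided] + 1L
    # two-sided binomial decisions on accumulated hits
    for (f in undecided) {
      p_hi <- stats::pbinom(hits[f] - 1L, tested[f], 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], tested[f], 0.5)
      if (p_hi < alpha_bonf) status[f] <- "confirmed"
      else if (p_lo < alpha_bonf) status[f] <- "rejected"
    }
  }

  tentative <- feats[status == "undecided"]
  resolved <- data.frame(feature = character(0), median_importance = numeric(0),
                         median_shadow_max = numeric(0),
                         decision = character(0), stringsAsFactors = FALSE)
  if (length(tentative)) {
    med_shadow <- stats::median(shadow_hist[seq_len(r)], na.rm = TRUE)
    for (f in tentative) {
      med_f <- stats::median(imp_hist[seq_len(r), f], na.rm = TRUE)
      dec <- if (is.finite(med_f) && med_f > med_shadow) "confirmed" else "rejected"
      status[f] <- dec
      resolved <- rbind(resolved, data.frame(
        feature = f, median_importance = med_f,
        median_shadow_max = med_shadow, decision = dec,
        stringsAsFactors = FALSE))
    }
  }

  structure(list(confirmed = feats[status == "confirmed"],
                 tentative = character(0),
                 rejected = feats[status == "rejected"],
                 tentative_resolved = resolved,
                 importance_history = imp_hist[seq_len(r), , drop = FALSE],
                 shadow_max_history = shadow_hist[seq_len(r)],
                 hits = hits, rounds_tested = tested,
                 rounds = r, seed = seed, alpha = alpha,
                 num_trees = num_trees),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d rounds: %d confirmed, %d rejected\n",
              x$rounds, length(x$confirmed), length(x$rejected)))
  if (length(x$confirmed))
    cat("confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  invisible(x)
}

#' Mean per-feature importance from a selection result
#'
#' Mean random-forest permutation importance across the rounds in which each
#' feature participated; used as the ordering for correlation pruning.
#' @param result a `boruta_result`.
#' @return Named numeric vector.
#' @export
selection_importance <- function(result) {
  stopifnot(inherits(result, "boruta_result"))
  colMeans(result$importance_history, na.rm = TRUE)
}

#' Prune correlated features
#'
#' Greedy pass in descending importance: a feature is kept iff its absolute
#' Pearson correlation with every already-kept feature is below the
#' threshold. The retained set therefore has all pairwise `|r| < r_threshold`
#' and, within any correlated group, keeps the most important member.
#'
#' @param X data.frame or matrix containing (at least) `features` columns.
#' @param features candidate feature names (e.g. the confirmed set).
#' @param r_threshold absolute Pearson correlation threshold (default 0.6).
#' @param importance named numeric vector ordering the candidates (larger =
#'   kept first); defaults to the order given.
#' @return List with `retained` (character vector, in processing order) and
#'   `prune_log` (data.frame `dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(X, features, r_threshold = 0.6,
                             importance = NULL) {
  X <- as.data.frame(X)
  missing_f <- setdiff(features, colnames(X))
  if (length(missing_f))
    stop("features not in X: ", paste(missing_f, collapse = ", "))
  if (is.null(importance))
    importance <- stats::setNames(rev(seq_along(features)), features)
  ord <- features[order(-importance[features])]
  kept <- character(0)
  log <- data.frame(dropped = character(0), kept = character(0),
                    r = numeric(0), stringsAsFactors = FALSE)
  for (f in ord) {
    if (length(kept) == 0L) { kept <- f; next }
    rs <- vapply(kept, function(k) {
      suppressWarnings(stats::cor(X[[f]], X[[k]]))
    }, 0.0)
    rs[is.na(rs)] <- 1  # constant column vs anything: treat as redundant
    if (all(abs(rs) < r_threshold)) {
      kept <- c(kept, f)
    } else {
      w <- which.max(abs(rs))
      log <- rbind(log, data.frame(dropped = f, kept = kept[w],
                                   r = rs[w], stringsAsFactors = FALSE))
    }
  }
  list(retained = kept, prune_log = log)
}

#' The frozen six-feature panel of the reference study
#'
#' The published CD3-associated feature set (all from T1 post-contrast):
#' histogram kurtosis, NGTDM contrast, and four size-zone features. Shipped
#' as a packaged JSON resource so the downstream classifier can be run
#' without re-running selection.
#'
#' @return Character vector of 6 feature names.
#' @export
paper_feature_set <- function() {
  path <- system.file("extdata", "paper_feature_set.json",
                      package = "cd3radiomics")
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Serialize a selection result to JSON
#' @param result a `boruta_result` (optionally with pruning applied).
#' @param path output file.
#' @param pruned optional output of [prune_correlated()].
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path, pruned = NULL) {
  obj <- list(confirmed = result$confirmed, rejected = result$rejected,
              rounds = result$rounds, seed = result$seed,
              alpha = result$alpha,
              importance = as.list(selection_importance(result)))
  if (!is.null(pruned)) {
    obj$retained <- pruned$retained
    obj$prune_log <- pruned$prune_log
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
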