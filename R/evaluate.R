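#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs ranked
#' concordantly, ties counted 1/2 — equivalently `U / (n_pos * n_neg)`.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or `"high"`/`"low"` with
#'   `"high"` positive). Both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases within each class independently (so every resample retains
#' both classes) and returns the percentile interval of the bootstrap AUCs.
#'
#' @param scores,labels as in [roc_auc()].
#' @param B bootstrap replicates (>= 100; default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, B = 2000L, level = 0.95,
                             seed = 1L) {
  if (B < 100L) stop("B must be >= 100")
  y <- as_binary01(labels)
  ipos <- which(y == 1L); ineg <- which(y == 0L)
  if (!length(ipos) || !length(ineg)) stop("both classes must be present")
  set.seed(seed)
  aucs <- vapply(seq_len(B), function(b) {
    ii <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    roc_auc(scores[ii], y[ii])
  }, 0.0)
  a <- (1 - level) / 2
  unname(stats::quantile(aucs, c(a, 1 - a)))
}

#' Construct a confusion matrix
#'
#' "High infiltration" is the positive class throughout.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; or leave these missing and
#'   supply `predicted` and `actual` label vectors instead.
#' @param predicted,actual label vectors (`"high"`/`"low"`, logical or 0/1).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                             predicted = NULL, actual = NULL) {
  if (!is.null(predicted)) {
    p <- as_binary01(predicted); a <- as_binary01(actual)
    tp <- sum(p == 1 & a == 1); fp <- sum(p == 1 & a == 0)
    tn <- sum(p == 0 & a == 0); fn <- sum(p == 0 & a == 1)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(prediction = c("low", "high"),
                              actual = c("low", "high")))
  print(m)
  invisible(x)
}

#' Confusion-matrix metrics with exact binomial CI
#'
#' Accuracy `(TP+TN)/n` with its two-sided exact Clopper-Pearson 95% CI
#' (via `binom.test`), sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`
#' and the classifier's false discovery rate `FP/(TP+FP)`. An empty
#' predicted-positive set leaves FDR as `NA` with `fdr_undefined = TRUE`.
#'
#' @param cm a [confusion_matrix].
#' @param level confidence level for the accuracy CI.
#' @return List with `accuracy`, `accuracy_ci` (lo, hi), `sensitivity`,
#'   `specificity`, `fdr`, `fdr_undefined`, `n`.
#' @export
confusion_metrics <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  correct <- cm$tp + cm$tn
  bt <- stats::binom.test(correct, n, conf.level = level)
  fdr_undef <- (cm$tp + cm$fp) == 0
  list(accuracy = correct / n,
       accuracy_ci = unname(bt$conf.int),
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       fdr = if (fdr_undef) NA_real_ else cm$fp / (cm$tp + cm$fp),
       fdr_undefined = fdr_undef,
       n = n)
}

#' Spearman concordance between scores and a continuous outcome
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic, so tied data are handled uniformly).
#'
#' @param scores numeric model predictions.
#' @param y_continuous numeric outcome (e.g. CD3 z-scores or counts).
#' @return List with `rho` and `p_value`.
#' @export
spearman_concordance <- function(scores, y_continuous) {
  if (length(scores) < 3L) stop("need n >= 3")
  if (stats::var(scores) == 0 || stats::var(y_continuous) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- stats::cor.test(scores, y_continuous, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Covariate-adjusted regression of CD3 on model predictions
#'
#' A single multivariate linear model of the continuous CD3 outcome on the
#' clinical covariates, tumor volumetrics and the model predictions; reports
#' one p-value per term. Set `family = "binomial"` for a logistic model on a
#' binary outcome instead.
#'
#' @param y outcome (continuous CD3 z-scores; or binary for logistic).
#' @param predictions model prediction scores.
#' @param covariates data.frame of adjustment variables (e.g. age, sex, KPS,
#'   per-modality tumor volume and total intensity).
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @return data.frame with `variable` and `p_value`, covariates first and the
#'   prediction term last.
#' @export
covariate_adjusted_regression <- function(y, predictions, covariates,
                                          family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  covariates <- as.data.frame(covariates)
  df <- cbind(covariates, model_prediction = predictions)
  if (anyNA(df) || anyNA(y)) stop("complete cases required")
  if (nrow(df) <= ncol(df) + 1L)
    stop("need n > number of predictors + 1")
  df$.y <- y
  fit <- if (family == "gaussian") stats::lm(.y ~ ., data = df)
         else stats::glm(.y ~ ., data = df, family = stats::binomial())
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al) > 0)
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al), collapse = ", "))
  sm <- if (family == "gaussian") summary(fit)$coefficients
        else summary(fit)$coefficients
  terms <- rownames(sm)
  terms <- terms[terms != "(Intercept)"]
  pcol <- ncol(sm)
  data.frame(variable = terms, p_value = sm[terms, pcol],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis balance tests between two groups
#'
#' One two-group rank test per variable; constant variables are flagged and
#' their p omitted (`NA`).
#'
#' @param groupA,groupB data.frames with the variables as columns.
#' @param variables character vector of column names to test.
#' @return data.frame with `variable`, `p_value`, `constant`.
#' @export
kruskal_wallis_balance <- function(groupA, groupB, variables) {
  if (nrow(groupA) == 0L || nrow(groupB) == 0L)
    stop("both groups must be nonempty")
  g <- factor(c(rep("A", nrow(groupA)), rep("B", nrow(groupB))))
  out <- lapply(variables, function(v) {
    x <- c(rank_safe(groupA[[v]]), rank_safe(groupB[[v]]))
    if (length(unique(x)) == 1L)
      return(data.frame(variable = v, p_value = NA_real_, constant = TRUE,
                        stringsAsFactors = FALSE))
    kw <- stats::kruskal.test(x, g)
    data.frame(variable = v, p_value = kw$p.value, constant = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# categorical variables enter the rank test via integer coding
rank_safe <- function(x) {
  if (is.numeric(x)) x else as.integer(factor(x))
}

#' Paired bootstrap comparison of two AUCs
#'
#' Tests the difference in AUC of two score vectors on the same cases (e.g.
#' a volumetrics-only model against a combined model). Cases are resampled
#' jointly; the two-sided p-value is the normal tail of the observed
#' difference standardized by the bootstrap standard deviation. Identical
#' score vectors give p = 1.
#'
#' @param scores_a,scores_b two score vectors on the same cases.
#' @param labels binary labels for those cases.
#' @param B bootstrap replicates (>= 100; default 2000).
#' @param seed integer seed.
#' @return List with `p_value`, `auc_a`, `auc_b`, `diff`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels, B = 2000L,
                                  seed = 1L) {
  if (B < 100L) stop("B must be >= 100")
  y <- as_binary01(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("score vectors and labels must have the same length")
  auc_a <- roc_auc(scores_a, y)
  auc_b <- roc_auc(scores_b, y)
  d_obs <- auc_a - auc_b
  set.seed(seed)
  n <- length(y)
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      ii <- sample.int(n, replace = TRUE)
      if (length(unique(y[ii])) == 2L) break
    }
    diffs[b] <- roc_auc(scores_a[ii], y[ii]) - roc_auc(scores_b[ii], y[ii])
  }
  s <- stats::sd(diffs)
  p <- if (s == 0) 1 else 2 * stats::pnorm(-abs(d_obs) / s)
  list(p_value = p, auc_a = auc_a, auc_b = auc_b, diff = d_obs)
}

#' Full evaluation report for a trained model on a test set
#'
#' Assembles the evaluation statistics of the study design: test ROC AUC with
#' stratified bootstrap CI, confusion-matrix metrics at the model's decision
#' threshold with exact binomial accuracy CI, Spearman concordance between
#' scores and the continuous CD3 outcome, and (when covariates are supplied)
#' the covariate-adjusted regression p-values.
#'
#' @param model a `cd3_model`.
#' @param test_X test-set features.
#' @param test_y binary test labels.
#' @param test_cd3_z continuous CD3 outcome for concordance (optional).
#' @param covariates optional data.frame for the adjusted regression.
#' @param B,level,seed bootstrap parameters.
#' @return Object of class `eval_report` (a list).
#' @export
evaluate_model <- function(model, test_X, test_y, test_cd3_z = NULL,
                           covariates = NULL, B = 2000L, level = 0.95,
                           seed = 1L) {
  pred <- predict(model, test_X)
  y01 <- as_binary01(test_y)
  auc <- roc_auc(pred$score, y01)
  ci <- auc_bootstrap_ci(pred$score, y01, B = B, level = level, seed = seed)
  cm <- confusion_matrix(predicted = pred$label, actual = test_y)
  met <- confusion_metrics(cm, level = level)
  rep <- list(auc = auc, auc_ci = ci, confusion = cm,
              accuracy = met$accuracy, accuracy_ci = met$accuracy_ci,
              sensitivity = met$sensitivity, specificity = met$specificity,
              fdr = met$fdr, n = met$n)
  if (!is.null(test_cd3_z)) {
    sp <- spearman_concordance(pred$score, test_cd3_z)
    rep$spearman_rho <- sp$rho
    rep$spearman_p <- sp$p_value
  }
  if (!is.null(covariates) && !is.null(test_cd3_z))
    rep$adjusted_regression <-
      covariate_adjusted_regression(test_cd3_z, pred$score, covariates)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f, %.3f]\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("accuracy %.1f%% [%.3f, %.3f]; sensitivity %.1f%%; specificity %.1f%%; FDR %s\n",
              100 * x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
              100 * x$sensitivity, 100 * x$specificity,
              if (is.na(x$fdr)) "undefined" else sprintf("%.1f%%", 100 * x$fdr)))
  if (!is.null(x$spearman_rho))
    cat(sprintf("Spearman rho %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  if (!is.null(x$adjusted_regression)) {
    cat("covariate-adjusted regression p-values:\n")
    print(x$adjusted_regression, row.names = FALSE)
  }
  invisible(x)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity at every distinct threshold, suitable for CSV
#' export or plotting.
#' @param scores,labels as in [roc_auc()].
#' @return data.frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary01(labels)
  ths <- c(-Inf, sort(unique(scores)))
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  do.call(rbind, lapply(ths, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & y == 1L) / npos,
               specificity = sum(!pred & y == 0L) / nneg)
  }))
}
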