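oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("roc_auc matches hand cases including ties", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(0, 0, 1, 1)), 0.25)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("roc_auc equals the brute-force pairwise oracle on random small inputs", {
  for (s in 1:60) {
    set.seed(s)
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("stratified bootstrap CI is deterministic, covers the point AUC, and tightens when separation is perfect", {
  set.seed(1)
  scores <- c(rnorm(200, 2), rnorm(200, -2))
  labels <- c(rep(1, 200), rep(0, 200))
  ci <- auc_bootstrap_ci(scores, labels, B = 500, seed = 3)
  expect_identical(ci, auc_bootstrap_ci(scores, labels, B = 500, seed = 3))
  expect_true(ci[1] >= 0.99 && ci[2] <= 1)
  for (s in 1:5) {
    set.seed(s)
    sc <- rnorm(60)
    lb <- rbinom(60, 1, 0.5)
    if (length(unique(lb)) < 2) next
    point <- roc_auc(sc, lb)
    ci2 <- auc_bootstrap_ci(sc, lb, B = 400, seed = s)
    expect_true(ci2[1] <= point && point <= ci2[2])
  }
  expect_error(auc_bootstrap_ci(scores, labels, B = 50), "100")
})

test_that("confusion metrics reproduce the published testing-cohort rates", {
  cm <- confusion_matrix(tp = 16, fp = 2, tn = 10, fn = 6)
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy, 26 / 34)
  expect_equal(round(100 * met$accuracy, 1), 76.5)
  expect_equal(round(100 * met$sensitivity, 1), 72.7)
  expect_equal(round(100 * met$specificity, 2), 83.33)
  expect_equal(round(100 * met$fdr, 1), 11.1)
  expect_equal(round(met$accuracy_ci[1], 3), 0.588)
  expect_equal(round(met$accuracy_ci[2], 3), 0.893)
})

test_that("confusion metrics reproduce the published training-cohort rates", {
  cm <- confusion_matrix(tp = 15, fp = 0, tn = 19, fn = 1)
  met <- confusion_metrics(cm)
  expect_equal(round(100 * met$accuracy, 1), 97.1)
  expect_equal(met$sensitivity, 15 / 16)
  expect_equal(round(100 * met$sensitivity, 2), 93.75)
  expect_equal(met$specificity, 1)
  expect_equal(met$fdr, 0)
})

test_that("confusion edge cases: all-correct CI hits 1; empty positives flag FDR", {
  met <- confusion_metrics(confusion_matrix(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(met$accuracy, 1)
  expect_equal(met$accuracy_ci[2], 1)
  met2 <- confusion_metrics(confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(met2$fdr_undefined)
  expect_true(is.na(met2$fdr))
})

test_that("accuracy CI is exact Clopper-Pearson with nominal coverage at n = 34", {
  set.seed(12)
  p <- 0.75
  n <- 34
  covered <- vapply(1:2000, function(i) {
    k <- rbinom(1, n, p)
    ci <- stats::binom.test(k, n)$conf.int
    ci[1] <= p && p <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.95)
})

test_that("Spearman concordance matches hand ranks and flags constants", {
  expect_equal(spearman_concordance(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_concordance(1:5, 5:1)$rho, -1)
  expect_equal(spearman_concordance(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_error(spearman_concordance(rep(1, 5), 1:5), "constant")
})

test_that("covariate-adjusted regression isolates a true prediction signal", {
  set.seed(31)
  n <- 100
  cov <- data.frame(age = rnorm(n, 60, 10), sex = sample(c("F", "M"), n, TRUE),
                    kps = rnorm(n, 80, 10))
  pred <- rnorm(n)
  out <- suppressWarnings(covariate_adjusted_regression(pred, pred, cov))
  expect_lt(out$p_value[out$variable == "model_prediction"], 0.001)
  expect_equal(min(out$p_value), out$p_value[out$variable == "model_prediction"])
})

test_that("the adjusted prediction p-value is null-calibrated under independence", {
  set.seed(32)
  rejections <- vapply(1:500, function(i) {
    n <- 40
    cov <- data.frame(age = rnorm(n), kps = rnorm(n))
    y <- rnorm(n)
    pred <- rnorm(n)
    out <- covariate_adjusted_regression(y, pred, cov)
    out$p_value[out$variable == "model_prediction"] < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.12)
})

test_that("the full-covariate regression reports the eight study variables", {
  set.seed(33)
  n <- 60
  cov <- data.frame(age = rnorm(n, 60, 12), sex = sample(c("F", "M"), n, TRUE),
                    kps = rnorm(n, 80, 10),
                    flair_volume = rexp(n), flair_total_intensity = rexp(n),
                    t1post_volume = rexp(n), t1post_total_intensity = rexp(n))
  out <- covariate_adjusted_regression(rnorm(n), rnorm(n), cov)
  expect_equal(nrow(out), 8)
  expect_true("model_prediction" %in% out$variable)
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  set.seed(34)
  n <- 50
  cov <- data.frame(age = rnorm(n))
  cov$age_copy <- cov$age
  expect_error(covariate_adjusted_regression(rnorm(n), rnorm(n), cov),
               "age_copy")
})

test_that("Kruskal-Wallis balance behaves on identical, shifted and constant inputs", {
  a <- data.frame(v = rnorm(50, 0, 1), w = rep(1, 50))
  b <- a
  out <- kruskal_wallis_balance(a, b, c("v", "w"))
  expect_gte(out$p_value[out$variable == "v"], 0.99)
  expect_true(out$constant[out$variable == "w"])
  expect_true(is.na(out$p_value[out$variable == "w"]))
  set.seed(2)
  b2 <- data.frame(v = rnorm(50, 3, 1), w = rep(1, 50))
  out2 <- kruskal_wallis_balance(a, b2, "v")
  expect_lt(out2$p_value, 0.001)
})

test_that("paired bootstrap AUC comparison separates perfect from random scores", {
  set.seed(14)
  labels <- rep(c(0, 1), 50)
  perfect <- labels + rnorm(100, 0, 0.05)
  random <- rnorm(100)
  out <- compare_auc_bootstrap(perfect, random, labels, B = 400, seed = 2)
  expect_lt(out$p_value, 0.01)
  same <- compare_auc_bootstrap(perfect, perfect, labels, B = 200, seed = 2)
  expect_equal(same$p_value, 1)
  out2 <- compare_auc_bootstrap(perfect, random, labels, B = 400, seed = 2)
  expect_identical(out$p_value, out2$p_value)
  expect_error(compare_auc_bootstrap(perfect, random, labels, B = 50), "100")
})

test_that("evaluate_model assembles a consistent report", {
  set.seed(15)
  d <- data.frame(x1 = rnorm(60))
  y <- ifelse(d$x1 + rnorm(60, 0, 0.5) > 0, "high", "low")
  m <- fit_logistic(d, y)
  rep <- evaluate_model(m, d, y, test_cd3_z = d$x1 + rnorm(60, 0, 0.5),
                        B = 300, seed = 4)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_true(all(c(rep$accuracy, rep$sensitivity, rep$specificity) >= 0))
  expect_true(all(c(rep$accuracy, rep$sensitivity, rep$specificity) <= 1))
  expect_output(print(rep), "AUC")
})
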