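#' Pipeline configuration
#'
#' A validated configuration object for the end-to-end pipeline. Every
#' stochastic stage has its own explicit seed so stages can be re-run in
#' isolation; stage outputs are pure functions of (inputs, config, seeds).
#'
#' @param out_dir directory for stage artifacts.
#' @param n_patients synthetic cohort size.
#' @param gray_levels quantization levels G (>= 2).
#' @param target_mm isotropic reslicing target (mm).
#' @param icc_threshold robustness retention threshold in `[0, 1]`.
#' @param r_threshold correlation-pruning threshold in `(0, 1]`.
#' @param feature_source `"auto"` (use the selection result, falling back to
#'   the frozen published panel when selection confirms nothing) or
#'   `"paper"` (always the frozen panel).
#' @param engine classifier engine, `"gp"` or `"logistic"`.
#' @param boruta list of selection parameters (`max_rounds`, `alpha`,
#'   `num_trees`).
#' @param gp a [gp_params()] list.
#' @param bootstrap_B bootstrap replicates for evaluation.
#' @param seeds named list of per-stage seeds: `simulate`, `robustness`,
#'   `select`, `split`, `train`, `evaluate`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cd3pipe"),
                            n_patients = 20L,
                            gray_levels = 8L,
                            target_mm = 1.0,
                            icc_threshold = 0.6,
                            r_threshold = 0.6,
                            feature_source = c("auto", "paper"),
                            engine = c("gp", "logistic"),
                            boruta = list(max_rounds = 100L, alpha = 0.01,
                                          num_trees = 500L),
                            gp = gp_params(),
                            bootstrap_B = 2000L,
                            seeds = list(simulate = 1L, robustness = 2L,
                                         select = 3L, split = 4L,
                                         train = 5L, evaluate = 6L)) {
  feature_source <- match.arg(feature_source)
  engine <- match.arg(engine)
  fail <- function(field, msg) stop("config field '", field, "': ", msg)
  if (!is.numeric(n_patients) || n_patients < 2) fail("n_patients", "must be >= 2")
  if (!is.numeric(gray_levels) || gray_levels < 2)
    fail("gray_levels", "must be an integer >= 2")
  if (!is.numeric(target_mm) || target_mm <= 0)
    fail("target_mm", "must be positive")
  if (!is.numeric(icc_threshold) || icc_threshold < 0 || icc_threshold > 1)
    fail("icc_threshold", "must be in [0, 1]")
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold > 1)
    fail("r_threshold", "must be in (0, 1]")
  if (!is.numeric(bootstrap_B) || bootstrap_B < 100)
    fail("bootstrap_B", "must be >= 100")
  need_seeds <- c("simulate", "robustness", "select", "split", "train",
                  "evaluate")
  miss <- setdiff(need_seeds, names(seeds))
  if (length(miss)) fail("seeds", paste("missing:", paste(miss, collapse = ", ")))
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 gray_levels = as.integer(gray_levels),
                 target_mm = target_mm, icc_threshold = icc_threshold,
                 r_threshold = r_threshold, feature_source = feature_source,
                 engine = engine, boruta = boruta, gp = gp,
                 bootstrap_B = as.integer(bootstrap_B),
                 seeds = lapply(seeds, as.integer)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$gp <- unclass(cfg$gp)
  cfg$out_dir <- NULL  # the hash identifies the analysis, not its location
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_stages <- function() {
  c("simulate", "extract", "robustness", "select", "train", "evaluate")
}

stage_path <- function(config, name) file.path(config$out_dir, name)

write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(stage = stage, config_hash = config_hash(config),
                   seeds = config$seeds,
                   package_version = as.character(utils::packageVersion("cd3radiomics")),
                   inputs = inputs, outputs = outputs)
  path <- stage_path(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

require_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing artifact '", path,
         "'; run stage '", produced_by, "' first")
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to NIfTI + manifest CSV), `extract`
#' (86-feature CSV), `robustness` (ICC report CSV + retained-set JSON),
#' `select` (all-relevant selection + correlation pruning, JSON), `train`
#' (split, fit, model JSON) and `evaluate` (evaluation report JSON + ROC
#' CSV), or `all`. Every stage writes a manifest (config hash, seeds, package
#' version) so re-runs are reproducible; feature/report artifacts are pure
#' functions of the config.
#'
#' @param stage one of [pipeline_stages()] or `"all"`.
#' @param config a [pipeline_config()].
#' @return The stage's principal artifact path(s), invisibly (for `"all"`,
#'   the evaluation report object).
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, c(pipeline_stages(), "all"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  if (stage == "all") {
    for (s in pipeline_stages()) run_stage(s, config)
    return(invisible(read_eval_report(config)))
  }
  t0 <- Sys.time()
  out <- switch(stage,
                simulate = stage_simulate(config),
                extract = stage_extract(config),
                robustness = stage_robustness(config),
                select = stage_select(config),
                train = stage_train(config),
                evaluate = stage_evaluate(config))
  message(sprintf("[cd3radiomics] stage %-10s done in %.1fs -> %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  paste(unlist(out), collapse = ", ")))
  invisible(out)
}

#' Run the full pipeline
#' @param config a [pipeline_config()].
#' @return The final `eval_report`, invisibly.
#' @export
run_pipeline <- function(config) run_stage("all", config)

stage_simulate <- function(config) {
  cdir <- stage_path(config, "cohort")
  cs <- cohort_spec(n_patients = config$n_patients,
                    seed = config$seeds$simulate)
  generate_cohort(cs, dir = cdir, keep_volumes = FALSE)
  write_manifest(config, "simulate", inputs = list(),
                 outputs = list(manifest = file.path(cdir, "manifest.csv")))
  list(manifest = file.path(cdir, "manifest.csv"))
}

read_cohort_manifest <- function(config, stage) {
  path <- require_artifact(file.path(stage_path(config, "cohort"),
                                     "manifest.csv"), stage, "simulate")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

stage_extract <- function(config) {
  man <- read_cohort_manifest(config, "extract")
  feats <- t(vapply(seq_len(nrow(man)), function(i) {
    extract_all(read_patient(man[i, ]), G = config$gray_levels,
                target_mm = config$target_mm)
  }, numeric(86L)))
  df <- cbind(data.frame(patient_id = man$patient_id,
                         stringsAsFactors = FALSE), as.data.frame(feats))
  path <- stage_path(config, "features.csv")
  utils::write.csv(df, path, row.names = FALSE)
  write_manifest(config, "extract", inputs = list(manifest = "cohort/manifest.csv"),
                 outputs = list(features = path))
  list(features = path)
}

stage_robustness <- function(config) {
  man <- read_cohort_manifest(config, "robustness")
  patients <- lapply(seq_len(nrow(man)), function(i) read_patient(man[i, ]))
  rb <- assess_robustness(patients, G = config$gray_levels,
                          target_mm = config$target_mm,
                          threshold = config$icc_threshold,
                          seed = config$seeds$robustness)
  rpath <- stage_path(config, "robustness.csv")
  utils::write.csv(rb$report, rpath, row.names = FALSE)
  spath <- stage_path(config, "robust_features.json")
  jsonlite::write_json(rb$retained, spath)
  write_manifest(config, "robustness",
                 inputs = list(manifest = "cohort/manifest.csv"),
                 outputs = list(report = rpath, retained = spath))
  list(report = rpath, retained = spath)
}

stage_select <- function(config) {
  fpath <- require_artifact(stage_path(config, "features.csv"), "select",
                            "extract")
  man <- read_cohort_manifest(config, "select")
  feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  rpath <- stage_path(config, "robust_features.json")
  candidates <- setdiff(colnames(feats), "patient_id")
  if (file.exists(rpath)) {
    robust <- unlist(jsonlite::read_json(rpath, simplifyVector = TRUE))
    if (length(robust)) candidates <- intersect(candidates, robust)
  }
  X <- feats[, candidates, drop = FALSE]
  sel <- boruta_select(X, man$cd3_z, max_rounds = config$boruta$max_rounds,
                       seed = config$seeds$select,
                       alpha = config$boruta$alpha,
                       num_trees = config$boruta$num_trees)
  pruned <- if (length(sel$confirmed))
    prune_correlated(X, sel$confirmed, config$r_threshold,
                     selection_importance(sel)) else NULL
  spath <- stage_path(config, "selection.json")
  write_selection(sel, spath, pruned)
  write_manifest(config, "select",
                 inputs = list(features = "features.csv"),
                 outputs = list(selection = spath))
  list(selection = spath)
}

selected_features <- function(config) {
  if (config$feature_source == "paper") return(paper_feature_set())
  spath <- stage_path(config, "selection.json")
  if (file.exists(spath)) {
    sel <- jsonlite::read_json(spath, simplifyVector = TRUE)
    retained <- unlist(sel$retained)
    if (length(retained) > 0) return(retained)
  }
  paper_feature_set()  # documented fallback when selection confirms nothing
}

stage_train <- function(config) {
  fpath <- require_artifact(stage_path(config, "features.csv"), "train",
                            "extract")
  man <- read_cohort_manifest(config, "train")
  feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  data <- cbind(man[, c("patient_id", "age", "sex", "kps", "cd3_z",
                        "cd3_label")],
                feats[, setdiff(colnames(feats), "patient_id")])
  sp <- split_train_test(data, seed = config$seeds$split)
  use <- selected_features(config)
  model <- if (config$engine == "gp")
    fit_symbolic(sp$train[, use, drop = FALSE], sp$train$cd3_label,
                 params = config$gp, seed = config$seeds$train)
  else
    fit_logistic(sp$train[, use, drop = FALSE], sp$train$cd3_label,
                 seed = config$seeds$train)
  mpath <- stage_path(config, "model.json")
  write_model(model, mpath)
  saveRDS(list(model = model, split = sp, features = use),
          stage_path(config, "train_state.rds"))
  bpath <- stage_path(config, "split_balance.csv")
  utils::write.csv(sp$balance, bpath, row.names = FALSE)
  write_manifest(config, "train",
                 inputs = list(features = "features.csv"),
                 outputs = list(model = mpath, balance = bpath))
  list(model = mpath)
}

stage_evaluate <- function(config) {
  state_path <- require_artifact(stage_path(config, "train_state.rds"),
                                 "evaluate", "train")
  st <- readRDS(state_path)
  test <- st$split$test
  covars <- test[, c("age", "sex", "kps",
                     "flair_regional_volume_mm3",
                     "flair_regional_total_intensity",
                     "t1post_regional_volume_mm3",
                     "t1post_regional_total_intensity")]
  rep <- evaluate_model(st$model, test[, st$features, drop = FALSE],
                        test$cd3_label, test_cd3_z = test$cd3_z,
                        covariates = covars, B = config$bootstrap_B,
                        seed = config$seeds$evaluate)
  epath <- stage_path(config, "eval_report.json")
  jsonlite::write_json(
    list(auc = rep$auc, auc_ci = rep$auc_ci, accuracy = rep$accuracy,
         accuracy_ci = rep$accuracy_ci, sensitivity = rep$sensitivity,
         specificity = rep$specificity, fdr = rep$fdr,
         spearman_rho = rep$spearman_rho, spearman_p = rep$spearman_p,
         n = rep$n,
         adjusted_regression = rep$adjusted_regression),
    epath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pred <- predict(st$model, test[, st$features, drop = FALSE])
  utils::write.csv(roc_points(pred$score, test$cd3_label),
                   stage_path(config, "roc_points.csv"), row.names = FALSE)
  saveRDS(rep, stage_path(config, "eval_report.rds"))
  write_manifest(config, "evaluate",
                 inputs = list(train_state = "train_state.rds"),
                 outputs = list(report = epath))
  list(report = epath)
}

read_eval_report <- function(config) {
  readRDS(stage_path(config, "eval_report.rds"))
}
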