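#' Random 50/50 train/test split with balance report
#'
#' Splits a labelled cohort into training and testing halves (training gets
#' the extra patient when n is odd). If either half lacks one of the two
#' classes the split is redrawn, up to `max_retries`. A Kruskal-Wallis
#' balance report (one p-value per checked variable) is emitted so the halves
#' can be verified comparable.
#'
#' @param data data.frame with a label column and the balance variables.
#' @param seed integer seed.
#' @param label_col name of the binary label column (default `"cd3_label"`).
#' @param balance_vars variables for the balance report; defaults to every
#'   numeric column except the label.
#' @param max_retries redraw cap when a class is missing from a half.
#' @return List with `train`, `test` (data.frames), `train_idx`, and
#'   `balance` (data.frame `variable`, `p_value`).
#' @export
split_train_test <- function(data, seed = 1L, label_col = "cd3_label",
                             balance_vars = NULL, max_retries = 100L) {
  n <- nrow(data)
  if (n < 4L) stop("need at least 4 labelled patients")
  lab <- data[[label_col]]
  if (is.null(lab)) stop("no label column '", label_col, "'")
  classes <- unique(lab)
  set.seed(seed)
  n_train <- ceiling(n / 2)
  for (try in seq_len(max_retries)) {
    idx <- sample.int(n, n_train)
    if (length(unique(lab[idx])) == length(classes) &&
        length(unique(lab[-idx])) == length(classes)) {
      train <- data[idx, , drop = FALSE]
      test <- data[-idx, , drop = FALSE]
      if (is.null(balance_vars)) {
        num <- vapply(data, is.numeric, TRUE)
        balance_vars <- setdiff(colnames(data)[num], label_col)
      }
      balance <- kruskal_wallis_balance(train, test, balance_vars)
      return(list(train = train, test = test, train_idx = sort(idx),
                  balance = balance))
    }
  }
  stop("could not draw a split with both classes in both halves after ",
       max_retries, " tries")
}

#' Genetic-programming hyperparameters
#'
#' @param population individuals per generation (default 500).
#' @param generations number of generations (default 50).
#' @param max_depth expression-tree depth cap (default 6).
#' @param tournament_size tournament selection size (default 3).
#' @param p_crossover,p_mutation subtree crossover/mutation probabilities;
#'   the remainder reproduces unchanged.
#' @param const_range ephemeral constant range.
#' @return List of class `gp_params`.
#' @export
gp_params <- function(population = 500L, generations = 50L, max_depth = 6L,
                      tournament_size = 3L, p_crossover = 0.8,
                      p_mutation = 0.15, const_range = c(-1, 1)) {
  stopifnot(population >= 2, generations >= 1, max_depth >= 2,
            tournament_size >= 1, p_crossover + p_mutation <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 max_depth = as.integer(max_depth),
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 const_range = const_range),
            class = "gp_params")
}

## ---- expression trees -----------------------------------------------------
## A node is list(op=, l=, r=) over {+, -, *, protected /}, list(var = name)
## or list(const = value). Protected division returns 1 where |denominator|
## is below 1e-9, keeping every expression finite on finite inputs.

GP_OPS <- c("+", "-", "*", "/")

new_terminal <- function(vars, const_range) {
  if (stats::runif(1) < 0.5)
    list(var = sample(vars, 1L))
  else
    list(const = stats::runif(1, const_range[1], const_range[2]))
}

random_tree <- function(vars, const_range, depth, full = FALSE) {
  if (depth <= 1L || (!full && stats::runif(1) < 0.3))
    return(new_terminal(vars, const_range))
  list(op = sample(GP_OPS, 1L),
       l = random_tree(vars, const_range, depth - 1L, full),
       r = random_tree(vars, const_range, depth - 1L, full))
}

tree_depth <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + max(tree_depth(node$l), tree_depth(node$r))
}

tree_size <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + tree_size(node$l) + tree_size(node$r)
}

# lexicographic parsimony: best fitness, ties broken toward smaller trees
# (standard GP bloat control; rank-based AUC on small samples ties often)
best_individual <- function(fitness, sizes) {
  top <- which(fitness == max(fitness))
  top[which.min(sizes[top])]
}

eval_tree <- function(node, data) {
  if (!is.null(node$var)) return(data[[node$var]])
  if (!is.null(node$const)) return(rep(node$const, nrow(data)))
  a <- eval_tree(node$l, data)
  b <- eval_tree(node$r, data)
  switch(node$op,
         "+" = a + b,
         "-" = a - b,
         "*" = a * b,
         "/" = ifelse(abs(b) < 1e-9, 1, a / b))
}

tree_string <- function(node) {
  if (!is.null(node$var)) return(node$var)
  if (!is.null(node$const)) return(sprintf("%.4g", node$const))
  sprintf("(%s %s %s)", tree_string(node$l), node$op, tree_string(node$r))
}

# enumerate subtree positions as integer paths; "" is the root
tree_paths <- function(node, prefix = "") {
  if (is.null(node$op)) return(prefix)
  c(prefix, tree_paths(node$l, paste0(prefix, "l")),
    tree_paths(node$r, paste0(prefix, "r")))
}

tree_get <- function(node, path) {
  if (path == "") return(node)
  for (ch in strsplit(path, "")[[1]]) node <- node[[ch]]
  node
}

tree_set <- function(node, path, sub) {
  if (path == "") return(sub)
  ch <- substr(path, 1, 1)
  node[[ch]] <- tree_set(node[[ch]], substr(path, 2, nchar(path)), sub)
  node
}

crossover_trees <- function(a, b, max_depth) {
  pa <- sample(tree_paths(a), 1L)
  pb <- sample(tree_paths(b), 1L)
  child <- tree_set(a, pa, tree_get(b, pb))
  if (tree_depth(child) > max_depth) a else child
}

mutate_tree <- function(a, vars, const_range, max_depth) {
  pa <- sample(tree_paths(a), 1L)
  sub <- random_tree(vars, const_range, depth = 3L)
  child <- tree_set(a, pa, sub)
  if (tree_depth(child) > max_depth) a else child
}

# rank-based AUC used as GP fitness (constant scores give 0.5)
auc_fitness <- function(scores, y01) {
  if (!all(is.finite(scores))) return(0)
  npos <- sum(y01 == 1L)
  nneg <- sum(y01 == 0L)
  r <- rank(scores)
  (sum(r[y01 == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

youden_threshold <- function(scores, y01) {
  cand <- sort(unique(scores))
  best_j <- -Inf
  best_t <- cand[1]
  npos <- sum(y01 == 1L)
  nneg <- sum(y01 == 0L)
  for (t in cand) {
    pred <- scores >= t
    j <- sum(pred & y01 == 1L) / npos + sum(!pred & y01 == 0L) / nneg - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}

#' Fit a symbolic-regression classifier by genetic programming
#'
#' Searches expression trees over `{+, -, *, protected /}` with the feature
#' columns and ephemeral constants as terminals, maximizing the training AUC
#' of the expression's continuous output against the binary labels
#' (tournament selection, subtree crossover and mutation, one-elite
#' survivorship, depth cap, and lexicographic parsimony pressure: selection
#' ties on fitness resolve toward the smaller tree, the usual bloat
#' control). The decision threshold is the Youden-optimal
#' point on the training ROC (ties broken toward the smallest threshold).
#' Fully deterministic given `seed`.
#'
#' @param train_X data.frame of training features (the model's terminals).
#' @param train_y binary training labels: logical, 0/1, or `"high"`/`"low"`
#'   (with `"high"` the positive class). Both classes must be present.
#' @param params a [gp_params()] list.
#' @param seed integer seed.
#' @return Object of class `cd3_model` with the fitted expression, threshold,
#'   fitness trace and training metadata.
#' @export
fit_symbolic <- function(train_X, train_y, params = gp_params(), seed = 1L) {
  train_X <- as.data.frame(train_X)
  train_X$patient_id <- NULL
  y01 <- as_binary01(train_y)
  if (length(unique(y01)) < 2L)
    stop("training labels contain a single class")
  if (nrow(train_X) != length(y01)) stop("X/y size mismatch")
  vars <- colnames(train_X)

  set.seed(seed)
  np <- params$population
  # ramped initialization: alternate grow/full at depths 2..4
  pop <- vector("list", np)
  for (i in seq_len(np))
    pop[[i]] <- random_tree(vars, params$const_range,
                            depth = 2L + (i %% 3L), full = i %% 2L == 0L)
  fitness <- vapply(pop, function(tr) auc_fitness(eval_tree(tr, train_X), y01),
                    0.0)
  sizes <- vapply(pop, tree_size, 0L)
  trace <- numeric(params$generations + 1L)
  trace[1] <- max(fitness)

  for (g in seq_len(params$generations)) {
    newpop <- vector("list", np)
    # elitism: carry the best individual over unchanged
    newpop[[1]] <- pop[[best_individual(fitness, sizes)]]
    tournament <- function() {
      ix <- sample.int(np, params$tournament_size, replace = TRUE)
      pop[[ix[best_individual(fitness[ix], sizes[ix])]]]
    }
    for (i in 2:np) {
      u <- stats::runif(1)
      newpop[[i]] <- if (u < params$p_crossover) {
        crossover_trees(tournament(), tournament(), params$max_depth)
      } else if (u < params$p_crossover + params$p_mutation) {
        mutate_tree(tournament(), vars, params$const_range, params$max_depth)
      } else {
        tournament()
      }
    }
    pop <- newpop
    fitness <- vapply(pop, function(tr) auc_fitness(eval_tree(tr, train_X), y01),
                      0.0)
    sizes <- vapply(pop, tree_size, 0L)
    trace[g + 1L] <- max(fitness)
  }

  best <- best_individual(fitness, sizes)
  expr <- pop[[best]]
  scores <- eval_tree(expr, train_X)
  structure(list(engine = "gp", expression = expr,
                 expression_string = tree_string(expr),
                 features = vars,
                 threshold = youden_threshold(scores, y01),
                 train_auc = fitness[best], fitness_trace = trace,
                 params = params, seed = seed, n_train = nrow(train_X)),
            class = "cd3_model")
}

#' Fit the transparent logistic-regression comparator
#'
#' Same interface and return class as [fit_symbolic()]: the score is the
#' linear predictor of a binomial GLM; the threshold is Youden-optimal on the
#' training data.
#'
#' @inheritParams fit_symbolic
#' @return Object of class `cd3_model` (engine `"logistic"`).
#' @export
fit_logistic <- function(train_X, train_y, seed = 1L) {
  train_X <- as.data.frame(train_X)
  train_X$patient_id <- NULL
  y01 <- as_binary01(train_y)
  if (length(unique(y01)) < 2L)
    stop("training labels contain a single class")
  df <- cbind(train_X, .y = y01)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  scores <- as.numeric(stats::predict(fit, newdata = train_X, type = "link"))
  structure(list(engine = "logistic", coefficients = stats::coef(fit),
                 glm_fit = fit, features = colnames(train_X),
                 threshold = youden_threshold(scores, y01),
                 train_auc = auc_fitness(scores, y01), seed = seed,
                 n_train = nrow(train_X)),
            class = "cd3_model")
}

as_binary01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("high", "low")))
    stop("character labels must be 'high'/'low'")
  as.integer(y == "high")
}

#' Predict CD3 infiltration scores and labels
#'
#' @param object a `cd3_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param type `"both"` (default: data.frame of score and label), `"score"`
#'   or `"label"`.
#' @param ... unused.
#' @return data.frame with `score` (continuous) and `label`
#'   (`"high"`/`"low"`, from `score >= threshold`), or the requested vector.
#' @export
predict.cd3_model <- function(object, newdata,
                              type = c("both", "score", "label"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f))
    stop("newdata is missing model features: ",
         paste(missing_f, collapse = ", "))
  scores <- if (object$engine == "gp") {
    eval_tree(object$expression, newdata)
  } else {
    as.numeric(stats::predict(object$glm_fit, newdata = newdata,
                              type = "link"))
  }
  labels <- ifelse(scores >= object$threshold, "high", "low")
  switch(type,
         score = scores,
         label = labels,
         both = data.frame(score = scores, label = labels,
                           stringsAsFactors = FALSE))
}

#' @export
print.cd3_model <- function(x, ...) {
  cat(sprintf("<cd3_model> engine=%s, %d training cases, training AUC %.3f\n",
              x$engine, x$n_train, x$train_auc))
  if (x$engine == "gp")
    cat("expression:", x$expression_string, "\n")
  cat(sprintf("decision threshold (Youden): %.4g\n", x$threshold))
  invisible(x)
}

#' @export
summary.cd3_model <- function(object, ...) {
  out <- list(engine = object$engine, n_train = object$n_train,
              train_auc = object$train_auc, threshold = object$threshold,
              features = object$features)
  if (object$engine == "gp") {
    out$expression <- object$expression_string
    out$fitness_trace <- object$fitness_trace
    out$depth <- tree_depth(object$expression)
  } else {
    out$coefficients <- object$coefficients
  }
  class(out) <- "summary.cd3_model"
  out
}

#' @export
print.summary.cd3_model <- function(x, ...) {
  cat(sprintf("CD3 infiltration classifier (%s)\n", x$engine))
  cat(sprintf("  training cases: %d, training AUC: %.3f, threshold: %.4g\n",
              x$n_train, x$train_auc, x$threshold))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  if (!is.null(x$expression))
    cat("  expression:", x$expression, "(depth", x$depth, ")\n")
  if (!is.null(x$coefficients)) {
    cat("  coefficients:\n")
    print(x$coefficients)
  }
  invisible(x)
}

#' Serialize a trained model to JSON
#' @param model a `cd3_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(engine = model$engine, features = model$features,
              threshold = model$threshold, train_auc = model$train_auc,
              seed = model$seed, n_train = model$n_train)
  if (model$engine == "gp") {
    obj$expression <- model$expression_string
    obj$params <- unclass(model$params)
  } else {
    obj$coefficients <- as.list(model$coefficients)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
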