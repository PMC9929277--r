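#' Specify a tree-based classifier
#'
#' One uniform contract over the three model families compared in the
#' study: a single entropy (information-gain) decision tree, a bagged
#' random forest with per-tree majority vote, and stagewise gradient
#' boosting of shallow regression trees under logistic loss.
#'
#' No hyperparameters were tuned for the study; the defaults are the
#' common library defaults of the era (forest: 100 trees, unlimited depth,
#' `mtry = floor(sqrt(p))`; boosting: 100 stages, depth 3, learning rate
#' 0.1) and are all overridable.
#'
#' @param family `"decision_tree"`, `"random_forest"` or
#'   `"gradient_boosting"`.
#' @param n_trees Number of trees (1 for the single tree; default 100 for
#'   the ensembles).
#' @param max_depth Maximum tree depth; `NULL` means effectively unlimited
#'   for the tree/forest and 3 for boosting.
#' @param learning_rate Shrinkage for boosting, in (0, 1].
#' @param mtry Features sampled per split; `NULL` means all features for
#'   the single tree and `floor(sqrt(p))` for the forest.
#' @param min_node Minimum node size eligible for splitting (default 2,
#'   i.e. grow to purity).
#' @param bootstrap Whether forest trees are grown on bootstrap resamples
#'   (default `TRUE`; disabling it with `n_trees = 1` and `mtry = p`
#'   reproduces the single decision tree).
#' @param min_hess Boosting only: minimum total hessian weight per leaf
#'   (the `min_child_weight = 1` regularisation standard in gradient
#'   boosting libraries). On a severely imbalanced table the per-row
#'   hessian `p(1-p)` is tiny, so this floor prevents the booster from
#'   isolating small minority pockets — the mechanism behind the
#'   characteristic all-negative boosted model on the original data.
#' @param seed RNG seed used by [train()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("decision_tree", "random_forest",
                                  "gradient_boosting"),
                       n_trees = NULL, max_depth = NULL, learning_rate = 0.1,
                       mtry = NULL, min_node = 2L, bootstrap = TRUE,
                       min_hess = 1, seed = 1L) {
  family <- match.arg(family)
  if (is.null(n_trees))
    n_trees <- if (family == "decision_tree") 1L else 100L
  if (n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  if (family == "gradient_boosting" &&
      (learning_rate <= 0 || learning_rate > 1))
    stop("`learning_rate` must be in (0, 1]", call. = FALSE)
  if (is.null(max_depth))
    max_depth <- if (family == "gradient_boosting") 3L else 30L
  structure(list(family = family, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, mtry = mtry,
                 min_node = as.integer(min_node), bootstrap = bootstrap,
                 min_hess = min_hess,
                 split_criterion = "entropy", seed = as.integer(seed)),
            class = "model_spec")
}

# Feature matrix and label vector from a feature table; the label column is
# `class_label`, everything else is a numeric predictor.
model_frame <- function(table, require_label = TRUE) {
  if (!is.data.frame(table)) stop("`table` must be a data frame", call. = FALSE)
  has_label <- "class_label" %in% names(table)
  if (require_label && !has_label)
    stop("table lacks a `class_label` column", call. = FALSE)
  feats <- setdiff(names(table), "class_label")
  X <- as.matrix(table[feats])
  if (!is.numeric(X)) stop("non-numeric feature columns", call. = FALSE)
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  list(X = X, y = if (has_label) as.numeric(table$class_label) else NULL,
       features = feats)
}

#' Train a tree-based classifier
#'
#' @param spec A [model_spec()].
#' @param table A feature table: numeric predictor columns plus a binary
#'   `class_label` column containing both classes.
#' @return An object of class `fitted_model` carrying the grown trees, the
#'   training-schema fingerprint (feature names, in order), and for
#'   boosting the intercept and the per-stage training deviance.
#' @export
train <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  mf <- model_frame(table)
  y <- mf$y
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("`class_label` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training table contains a single class", call. = FALSE)
  X <- mf$X
  n <- nrow(X); p <- ncol(X)
  set.seed(spec$seed)
  h1 <- rep(1, n)
  model <- list(spec = spec, features = mf$features,
                fingerprint = paste(mf$features, collapse = "|"))

  if (spec$family == "decision_tree") {
    mtry <- if (is.null(spec$mtry)) p else spec$mtry
    model$trees <- list(cpp_grow_tree(X, y, h1, seq_len(n) - 1L, mtry,
                                      spec$max_depth, spec$min_node, 0L))
  } else if (spec$family == "random_forest") {
    mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(p))) else spec$mtry
    model$trees <- lapply(seq_len(spec$n_trees), function(b) {
      rows <- if (spec$bootstrap) sample.int(n, n, replace = TRUE)
              else seq_len(n)
      cpp_grow_tree(X, y, h1, rows - 1L, mtry, spec$max_depth,
                    spec$min_node, 0L)
    })
  } else {  # gradient boosting, logistic loss, Newton leaf steps
    pbar <- mean(y)
    f0 <- log(pbar / (1 - pbar))
    Fv <- rep(f0, n)
    trees <- vector("list", spec$n_trees)
    loss <- numeric(spec$n_trees)
    rows0 <- seq_len(n) - 1L
    mtry <- if (is.null(spec$mtry)) p else spec$mtry
    for (m in seq_len(spec$n_trees)) {
      prob <- stats::plogis(Fv)
      g <- y - prob
      h <- pmax(prob * (1 - prob), 1e-12)
      tr <- cpp_grow_tree(X, g, h, rows0, mtry, spec$max_depth,
                          max(spec$min_node, 5L), 1L, spec$min_hess)
      step <- cpp_predict_tree(tr, X)
      Fv <- Fv + spec$learning_rate * step
      trees[[m]] <- tr
      prob <- stats::plogis(Fv)
      loss[m] <- -mean(y * log(pmax(prob, 1e-12)) +
                         (1 - y) * log(pmax(1 - prob, 1e-12)))
    }
    model$trees <- trees
    model$f0 <- f0
    model$train_loss <- loss
  }
  class(model) <- "fitted_model"
  model
}

# Reorders table columns to the training schema; refuses schema mismatches.
check_schema <- function(model, table) {
  feats <- model$features
  present <- setdiff(names(table), "class_label")
  if (!setequal(present, feats)) {
    stop("schema mismatch: model was trained on {",
         paste(feats, collapse = ", "), "} but table has {",
         paste(present, collapse = ", "), "}", call. = FALSE)
  }
  X <- as.matrix(table[feats])
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  X
}

#' Predict class-1 scores in [0, 1]
#'
#' For the decision tree the score is the leaf's class-1 fraction; for the
#' forest it is the fraction of trees voting class 1 (each tree votes by
#' its leaf majority); for boosting it is the logistic transform of the
#' additive ensemble margin.
#'
#' @param model A `fitted_model`.
#' @param table A feature table with the training schema (the
#'   `class_label` column, if present, is ignored).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "fitted_model"))
  X <- check_schema(model, table)
  switch(model$spec$family,
    decision_tree = cpp_predict_ensemble(model$trees, X, 0L),
    random_forest = cpp_predict_ensemble(model$trees, X, 1L),
    gradient_boosting = stats::plogis(
      model$f0 + model$spec$learning_rate *
        cpp_predict_ensemble(model$trees, X, 2L)))
}

#' Predict binary labels
#'
#' A row is labelled 1 when its score is at or above the threshold; the
#' boundary score of exactly 0.5 is assigned to class 1.
#'
#' @inheritParams predict_proba
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, table, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  as.integer(predict_proba(model, table) >= threshold)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted %s: %d tree(s), %d feature(s)\n",
              x$spec$family, length(x$trees), length(x$features)))
  invisible(x)
}
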