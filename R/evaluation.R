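#' Confusion matrix
#'
#' Counts true/false positives and negatives for an explicit positive
#' class. The study's headline tables are only jointly consistent when the
#' majority (ineffective) class is scored as positive, while the metric
#' definitions take the effective class as positive — so the positive
#' class is always named explicitly and swapping it swaps TP with TN and
#' FP with FN.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The label counted as positive (default 1, the
#'   effective class).
#' @return An object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `TN`, `FN` and `positive_class`.
#' @export
confusion <- function(truth, predicted, positive = 1) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fn <- sum(truth == positive & predicted != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 positive_class = positive),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean of the
#' two) and accuracy `(TP+TN)/total`. Undefined 0/0 ratios are reported
#' as 0, matching the convention under which an all-negative predictor
#' scores 0 recall, precision and F1.
#'
#' @param cm A [confusion()] matrix.
#' @return A named list with `accuracy`, `precision`, `recall`, `f1` and
#'   the `positive_class`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe(cm$TP, cm$TP + cm$FP)
  recall <- safe(cm$TP, cm$TP + cm$FN)
  f1 <- safe(2 * precision * recall, precision + recall)
  list(accuracy = (cm$TP + cm$TN) / total, precision = precision,
       recall = recall, f1 = f1, positive_class = cm$positive_class)
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin so fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a model on a dataset variant
#'
#' Runs the study's evaluation protocol: stratified folds, per-fold
#' confusion matrices and metrics, and their mean as the aggregate. Two
#' resampling placements are supported: `resample_before_cv` applies the
#' rebalancing transform once to the whole table before splitting (the
#' protocol the near-perfect published scores are characteristic of —
#' replicated or interpolated minority rows then land in test folds,
#' leaking information), while `resample_within_fold` rebalances each
#' training split only and is the methodologically sound alternative.
#'
#' @param spec A [model_spec()].
#' @param table A feature table.
#' @param k Number of folds (default 10).
#' @param resampler `NULL` or a function `(table, seed) ->
#'   resample_result` such as [random_oversample()], [smote()] or
#'   [random_undersample()].
#' @param leakage_mode `"resample_before_cv"` or `"resample_within_fold"`.
#' @param seed Master seed; fold assignment and per-fold model seeds are
#'   derived from it.
#' @param positive Positive class for the metrics (default 1).
#' @param threshold Decision threshold (default 0.5).
#' @param variant Free-text tag naming the dataset variant in the report.
#' @return An object of class `metrics_report`: `per_fold` (data frame of
#'   fold metrics), `aggregate` (mean over folds), `pooled` (confusion
#'   matrix pooled over folds), plus the protocol fields.
#' @export
cross_validate <- function(spec, table, k = 10, resampler = NULL,
                           leakage_mode = c("resample_before_cv",
                                            "resample_within_fold"),
                           seed = 1, positive = 1, threshold = 0.5,
                           variant = "original") {
  leakage_mode <- match.arg(leakage_mode)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(2147483646L, k + 2L)
  if (!is.null(resampler) && leakage_mode == "resample_before_cv")
    table <- resampler(table, seeds[k + 1L])$table
  y <- table$class_label
  fold <- stratified_folds(y, k, seeds[k + 2L])
  if (any(tabulate(fold, k) == 0) ||
      any(vapply(seq_len(k), function(f) length(unique(y[fold == f])), 1L)
          < length(unique(y))))
    stop("a fold is empty or missing a class; use fewer folds or more ",
         "data (stratification cannot fix counts below k)", call. = FALSE)

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train_tab <- table[fold != f, , drop = FALSE]
    if (!is.null(resampler) && leakage_mode == "resample_within_fold")
      train_tab <- resampler(train_tab, seeds[f])$table
    sp <- spec
    sp$seed <- seeds[f]
    fit <- train(sp, train_tab)
    test_tab <- table[fold == f, , drop = FALSE]
    pred <- predict_label(fit, test_tab, threshold)
    cm <- confusion(test_tab$class_label, pred, positive)
    m <- metrics(cm)
    rows[[f]] <- data.frame(fold = f, TP = cm$TP, FP = cm$FP, TN = cm$TN,
                            FN = cm$FN, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  aggregate <- colMeans(per_fold[c("accuracy", "precision", "recall", "f1")])
  pooled <- structure(list(TP = sum(per_fold$TP), FP = sum(per_fold$FP),
                           TN = sum(per_fold$TN), FN = sum(per_fold$FN),
                           positive_class = positive),
                      class = "confusion_matrix")
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 pooled = pooled, variant = variant, family = spec$family,
                 k = k, leakage_mode = leakage_mode,
                 positive_class = positive, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%s on %s (%d-fold, %s, positive = %s):\n  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
    x$family, x$variant, x$k, x$leakage_mode, x$positive_class,
    x$aggregate["accuracy"], x$aggregate["precision"],
    x$aggregate["recall"], x$aggregate["f1"]))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): TP %d  FP %d  TN %d  FN %d\n",
              x$positive_class, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
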