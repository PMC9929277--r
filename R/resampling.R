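#' @name resampling
#' @title Class-rebalancing transforms
#' @description
#' The three rebalancing transforms used in the experimental study:
#' random replication of the minority class, random removal of majority
#' rows, and SMOTE interpolation of synthetic minority rows. All three
#' return equal class counts, are deterministic under `seed`, and leave
#' the column schema unchanged.
NULL

class_counts <- function(table) {
  y <- table$class_label
  if (is.null(y)) stop("table lacks a `class_label` column", call. = FALSE)
  tab <- table(factor(y, levels = sort(unique(y))))
  if (length(tab) < 2L)
    stop("table contains a single class; rebalancing needs both",
         call. = FALSE)
  if (length(tab) > 2L) stop("class_label is not binary", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  list(counts = tab, minority = minority,
       majority = setdiff(names(tab), minority)[1])
}

resample_result <- function(table, provenance, seed) {
  structure(list(table = table, provenance = provenance, seed = seed),
            class = "resample_result")
}

#' Random minority oversampling
#'
#' Minority rows are randomly replicated (with replacement) until both
#' classes have equal counts; every original row is retained.
#'
#' @param table A feature table with a binary `class_label` containing
#'   both classes.
#' @param seed RNG seed.
#' @return A `resample_result`: `table`, a per-row `provenance` flag
#'   (`original` / `replicated` / `synthetic`) and the `seed`.
#' @export
random_oversample <- function(table, seed = 1) {
  cc <- class_counts(table)
  set.seed(seed)
  deficit <- as.integer(max(cc$counts) - min(cc$counts))
  min_idx <- which(table$class_label == as.numeric(cc$minority))
  extra <- if (deficit > 0) sample(min_idx, deficit, replace = TRUE)
           else integer(0)
  out <- rbind(table, table[extra, , drop = FALSE])
  resample_result(out,
                  c(rep("original", nrow(table)),
                    rep("replicated", length(extra))), seed)
}

#' Random majority under-sampling
#'
#' Majority rows are randomly removed until both classes have equal
#' counts; all minority rows are retained and the output preserves the
#' input row order.
#'
#' @inheritParams random_oversample
#' @export
random_undersample <- function(table, seed = 1) {
  cc <- class_counts(table)
  set.seed(seed)
  maj_idx <- which(table$class_label == as.numeric(cc$majority))
  keep_maj <- sort(sample(maj_idx, as.integer(min(cc$counts))))
  keep <- sort(c(which(table$class_label == as.numeric(cc$minority)),
                 keep_maj))
  resample_result(table[keep, , drop = FALSE],
                  rep("original", length(keep)), seed)
}

#' SMOTE: synthetic minority oversampling
#'
#' New minority rows are interpolated between a minority seed row and one
#' of its `k` nearest minority neighbours (Euclidean distance on z-scored
#' continuous features): `x_new = x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` on continuous features, while binary/one-hot
#' features (any column whose values all lie in \{0, 1\}) are copied from
#' the seed row, so fractional treatment flags never arise.
#'
#' @inheritParams random_oversample
#' @param k Neighbour count (default 5, as in the original SMOTE
#'   formulation); the minority class must have more than `k` rows.
#' @export
smote <- function(table, k = 5, seed = 1) {
  cc <- class_counts(table)
  set.seed(seed)
  min_lab <- as.numeric(cc$minority)
  min_idx <- which(table$class_label == min_lab)
  n_min <- length(min_idx)
  if (n_min <= k)
    stop("minority class has ", n_min, " rows but k = ", k,
         "; use a smaller `k`", call. = FALSE)
  deficit <- as.integer(max(cc$counts) - min(cc$counts))
  if (deficit == 0)
    return(resample_result(table, rep("original", nrow(table)), seed))

  feats <- setdiff(names(table), "class_label")
  Xmin <- as.matrix(table[min_idx, feats, drop = FALSE])
  is_binary <- vapply(feats, function(f)
    all(table[[f]] %in% c(0, 1)), TRUE)
  cont <- feats[!is_binary]

  # z-score continuous features of the minority set for the neighbour search
  Z <- Xmin[, cont, drop = FALSE]
  if (ncol(Z)) {
    mu <- colMeans(Z)
    sdv <- apply(Z, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Z <- sweep(sweep(Z, 2, mu), 2, sdv, "/")
  }
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(D[i, ])[seq_len(k)]))

  seeds <- rep_len(seq_len(n_min), deficit)      # round-robin over minority
  pick <- sample.int(ncol(nn), deficit, replace = TRUE)
  u <- stats::runif(deficit)
  new_rows <- table[min_idx[seeds], , drop = FALSE]
  for (f in cont) {
    xi <- Xmin[seeds, f]
    xn <- Xmin[nn[cbind(seeds, pick)], f]
    new_rows[[f]] <- xi + u * (xn - xi)
  }
  out <- rbind(table, new_rows)
  resample_result(out,
                  c(rep("original", nrow(table)),
                    rep("synthetic", deficit)), seed)
}

#' @export
print.resample_result <- function(x, ...) {
  tab <- table(x$table$class_label)
  cat(sprintf("resampled table: %d rows (%s), provenance: %s\n",
              nrow(x$table),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
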