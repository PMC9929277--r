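#' Per-day minutes above a temperature threshold
#'
#' For each calendar day, the cadence times the number of readings
#' strictly above the threshold ("higher than 40 degrees C" in the field
#' summaries, hence the strict inequality).
#'
#' @param series A [temperature_series()].
#' @param threshold Threshold in degrees C (default 40).
#' @return A data frame with `day` (Date) and `minutes`.
#' @export
time_above <- function(series, threshold = 40) {
  cad <- validate_series(series)
  day <- as.Date(series$time, tz = "UTC")
  agg <- tapply(series$temperature > threshold, day, function(z)
    cad * sum(z))
  data.frame(day = as.Date(names(agg)), minutes = as.numeric(agg),
             row.names = NULL)
}

#' Per-day degree-minutes above a base temperature
#'
#' The daily thermal dose: the positive temperature excess over the base,
#' summed over readings and weighted by the cadence, in degree-C minutes.
#' The default base is the 40-degree lethal threshold, so the dose is zero
#' on any day that never exceeds it.
#'
#' @param series A [temperature_series()].
#' @param base Base temperature in degrees C (default 40).
#' @return A data frame with `day` (Date) and `degree_minutes`.
#' @export
degree_minutes <- function(series, base = 40) {
  cad <- validate_series(series)
  day <- as.Date(series$time, tz = "UTC")
  agg <- tapply(pmax(0, series$temperature - base), day, function(z)
    cad * sum(z))
  data.frame(day = as.Date(names(agg)), degree_minutes = as.numeric(agg),
             row.names = NULL)
}

#' Daily thermal summaries per treatment
#'
#' @param series_list Named list of [temperature_series()] (one per
#'   treatment).
#' @param threshold Threshold/base temperature in degrees C.
#' @return A data frame with `treatment_id`, `day`,
#'   `minutes_above_threshold`, `degree_minutes`.
#' @export
treatment_daily_summary <- function(series_list, threshold = 40) {
  parts <- lapply(names(series_list), function(id) {
    ta <- time_above(series_list[[id]], threshold)
    dm <- degree_minutes(series_list[[id]], threshold)
    data.frame(treatment_id = id, day = ta$day,
               minutes_above_threshold = ta$minutes,
               degree_minutes = dm$degree_minutes)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

as_group_list <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups[[1]], groups[[2]])
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  lapply(groups, as.numeric)
}

#' Levene's test for homogeneity of variances
#'
#' Classical (mean-centred) Levene: a one-way ANOVA on the absolute
#' deviations from the group means; W is the resulting F statistic.
#'
#' @param groups A list of numeric vectors (>= 2 groups of >= 2
#'   observations each) or a two-column data frame (value, group).
#' @return A list with `W`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups) {
  groups <- as_group_list(groups)
  z <- lapply(groups, function(g) abs(g - mean(g)))
  val <- unlist(z, use.names = FALSE)
  grp <- factor(rep(seq_along(z), lengths(z)))
  N <- length(val); g <- nlevels(grp)
  zbar <- mean(val)
  zg <- tapply(val, grp, mean)
  ng <- tabulate(grp)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((val - zg[grp])^2)
  df1 <- g - 1L; df2 <- N - g
  W <- if (ss_within == 0) 0 else (ss_between / df1) / (ss_within / df2)
  list(W = W, df1 = df1, df2 = df2,
       p = stats::pf(W, df1, df2, lower.tail = FALSE))
}

# Compact letter display by insert-and-absorb: start from one letter
# covering everything; each significant pair splits every letter that
# contains both members; duplicate/contained letters are absorbed.
compact_letters <- function(sig, names) {
  g <- nrow(sig)
  cols <- list(rep(TRUE, g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] | !cols[[b]]) && !identical(cols[[a]], cols[[b]]))
        keep[b] <- FALSE
      if (a < b && keep[a] && keep[b] && identical(cols[[a]], cols[[b]]))
        keep[b] <- FALSE
    }
    cols <- cols[keep]
  }
  letters_out <- character(g)
  for (ci in seq_along(cols))
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]],
                                      letters[ci])
  stats::setNames(letters_out, names)
}

#' One-way ANOVA with Tukey-Kramer HSD and compact letters
#'
#' Classical one-way ANOVA (`F` on `g - 1` and `N - g` degrees of
#' freedom), followed by Tukey-Kramer pairwise comparisons (studentised
#' range with the unequal-sample-size correction, as implemented by
#' `stats::TukeyHSD`) and a compact letter display in which groups sharing
#' no letter differ at the chosen level.
#'
#' @param groups As in [levene_test()].
#' @param alpha Significance level for the letters (default 0.05).
#' @return An object of class `anova_tukey`: `F`, `df_between`,
#'   `df_within`, `p`, `means` (group mean, s.e.m., n, letter), `pairs`
#'   (Tukey-adjusted pairwise p-values and significance), `alpha`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  val <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(nm, lengths(groups)), levels = nm)
  fit <- stats::aov(val ~ grp)
  av <- summary(fit)[[1]]
  Fv <- av[1, "F value"]
  pv <- av[1, "Pr(>F)"]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  g <- length(groups)
  sig <- matrix(FALSE, g, g, dimnames = list(nm, nm))
  for (r in seq_len(nrow(pairs))) {
    ab <- strsplit(pairs$pair[r], "-", fixed = TRUE)[[1]]
    sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- pairs$significant[r]
  }
  letts <- compact_letters(sig, nm)
  means <- data.frame(
    group = nm,
    mean = vapply(groups, mean, 1),
    sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), 1),
    n = lengths(groups),
    letter = letts[nm], row.names = NULL)
  structure(list(F = Fv, df_between = g - 1L,
                 df_within = length(val) - g, p = pv, means = means,
                 pairs = pairs, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4f, P = %.4f\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Field-statistics report for a set of treatment series
#'
#' Convenience wrapper producing the study-style field summary: per-day
#' time above 40 degrees C and degree-minutes per treatment, Levene's
#' variance-homogeneity test and the ANOVA/Tukey letters for both daily
#' statistics.
#'
#' @param series_list Named list of [temperature_series()].
#' @param threshold Threshold/base temperature (default 40).
#' @param alpha Significance level (default 0.05).
#' @return A list with `daily`, `time_above` (list: `levene`, `anova`),
#'   `degree_minutes` (same shape).
#' @export
field_stats_report <- function(series_list, threshold = 40, alpha = 0.05) {
  daily <- treatment_daily_summary(series_list, threshold)
  by_treat <- function(col) split(daily[[col]], daily$treatment_id)
  ta <- by_treat("minutes_above_threshold")
  dm <- by_treat("degree_minutes")
  list(daily = daily,
       time_above = list(levene = levene_test(ta),
                         anova = anova_tukey(ta, alpha)),
       degree_minutes = list(levene = levene_test(dm),
                             anova = anova_tukey(dm, alpha)))
}
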