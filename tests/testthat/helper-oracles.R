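# Independent oracles and fixture builders shared across the suite.

t0 <- as.POSIXct("2018-07-26 00:00:00", tz = "UTC")

# Build a temperature series from a numeric vector at a given cadence.
make_series <- function(temps, cadence = 15, start = t0, ...) {
  temperature_series(start + 60 * cadence * (seq_along(temps) - 1L),
                     temps, ...)
}

# Brute-force per-minute scoring oracle: expand each reading into `cadence`
# one-minute ticks; every tick at binned level t contributes
# 1 / (D * 2^-(t - T)). Episode boundaries at readings below T.
oracle_raw_scores <- function(temps, threshold = 40, day_minutes = 1440,
                              bin_width = 1, cadence = 15) {
  scores <- numeric(0)
  acc <- 0
  in_ep <- FALSE
  for (temp in temps) {
    if (temp >= threshold) {
      in_ep <- TRUE
      lev <- threshold + floor((temp - threshold) / bin_width) * bin_width
      per_min <- 1 / (day_minutes * 2^(-(lev - threshold)))
      for (k in seq_len(cadence)) acc <- acc + per_min
    } else if (in_ep) {
      scores <- c(scores, acc)
      acc <- 0
      in_ep <- FALSE
    }
  }
  if (in_ep) scores <- c(scores, acc)
  scores
}

# Exhaustive Shapley oracle over feature subsets for an arbitrary
# prediction function, interventional value v(S) = mean_b f(x_S : b).
oracle_shap <- function(fun, x, background) {
  p <- length(x)
  phi <- numeric(p)
  idx <- seq_len(p)
  vcache <- new.env()
  vof <- function(S) {
    key <- paste0("k", paste(S, collapse = ","))
    if (!is.null(vcache[[key]])) return(vcache[[key]])
    Xs <- background
    if (length(S)) Xs[, S] <- matrix(x[S], nrow(background), length(S),
                                     byrow = TRUE)
    v <- mean(apply(Xs, 1, fun))
    vcache[[key]] <- v
    v
  }
  for (j in idx) {
    others <- setdiff(idx, j)
    for (k in 0:length(others)) {
      combs <- utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in combs)
        phi[j] <- phi[j] + w * (vof(sort(c(S, j))) - vof(S))
    }
  }
  phi
}

# One-way ANOVA from first-principles sums of squares.
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Classical Levene W: ANOVA F on |x - group mean|.
oracle_levene_W <- function(groups) {
  oracle_anova_F(lapply(groups, function(g) abs(g - mean(g))))
}

# Small separable toy table for model tests.
toy_table <- function(n = 40, gap = 4, seed = 99) {
  set.seed(seed)
  data.frame(x1 = c(rnorm(n / 2, 0), rnorm(n / 2, gap)),
             x2 = rnorm(n), x3 = as.numeric(runif(n) > 0.5),
             class_label = rep(c(0, 1), each = n / 2))
}

# Imbalanced toy table with an overlapping minority.
imbalanced_table <- function(n_maj = 120, n_min = 12, seed = 5) {
  set.seed(seed)
  data.frame(x1 = c(rnorm(n_maj, 0), rnorm(n_min, 2.5)),
             x2 = c(rnorm(n_maj), rnorm(n_min)),
             class_label = c(rep(0, n_maj), rep(1, n_min)))
}

# A fitted stump-like model whose behaviour we control exactly: replace the
# trees of a genuinely fitted forest with hand-built ones.
hand_model <- function(trees, features = c("x1", "x2", "x3"),
                       family = "decision_tree") {
  tab <- data.frame(x1 = c(0, 1, 0, 1), x2 = c(0, 0, 1, 1),
                    x3 = c(0, 1, 1, 0), class_label = c(0, 1, 0, 1))
  names(tab)[1:3] <- features
  fit <- train(model_spec(family, n_trees = max(1, length(trees)),
                          seed = 1), tab)
  fit$trees <- trees
  fit
}

stump <- function(var0, thr, lo, hi) {
  list(var = c(as.integer(var0), -1L, -1L), thr = c(thr, 0, 0),
       left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
       value = c(0, lo, hi), n = c(4L, 2L, 2L))
}

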