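test_that("daily time above threshold counts strict exceedances", {
  cold <- make_series(rep(35, 96))
  expect_equal(time_above(cold)$minutes, 0)

  temps <- c(rep(30, 40), rep(41, 10), rep(30, 46))
  ta <- time_above(make_series(temps))
  expect_equal(ta$minutes, 150)

  # boundary readings exactly at the threshold do not count
  ta40 <- time_above(make_series(c(rep(40, 96))))
  expect_equal(ta40$minutes, 0)

  # an infinitely low threshold counts the whole day
  expect_equal(time_above(make_series(rep(20, 96)), threshold = -Inf)$minutes,
               1440)

  # two calendar days are summarised separately
  two <- make_series(c(rep(41, 96), rep(30, 96)))
  ta2 <- time_above(two)
  expect_equal(ta2$minutes, c(1440, 0))
})

test_that("degree-minutes integrate the positive excess only", {
  expect_equal(degree_minutes(make_series(rep(38, 96)))$degree_minutes, 0)
  one_hot <- c(rep(30, 50), 42, rep(30, 45))
  expect_equal(degree_minutes(make_series(one_hot))$degree_minutes,
               (42 - 40) * 15)
  # linearity: doubling every exceedance doubles the dose
  temps <- c(rep(30, 50), 41, 43, 44, rep(30, 43))
  d1 <- degree_minutes(make_series(temps))$degree_minutes
  temps2 <- ifelse(temps > 40, 40 + 2 * (temps - 40), temps)
  d2 <- degree_minutes(make_series(temps2))$degree_minutes
  expect_equal(d2, 2 * d1)
  # dose is zero whenever time-above is zero (same base)
  s <- make_series(runif(96, 20, 39))
  expect_equal(degree_minutes(s)$degree_minutes, 0)
  expect_equal(time_above(s)$minutes, 0)
})

test_that("Levene's statistic matches the classical hand formula", {
  g_id <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(levene_test(g_id)$W, 0)

  set.seed(8)
  g <- list(a = rnorm(8, sd = 1), b = rnorm(10, sd = 3), c = rnorm(7))
  lv <- levene_test(g)
  expect_equal(lv$W, oracle_levene_W(g), tolerance = 1e-12)
  expect_equal(lv$df1, 2)
  expect_equal(lv$df2, 22)
  expect_true(lv$p >= 0 && lv$p <= 1)

  # inflating one group's scale increases W
  g_wide <- g
  g_wide$b <- g$b * 4
  expect_gt(levene_test(g_wide)$W, lv$W)

  expect_error(levene_test(list(a = 1:3)), "2 groups")
  expect_error(levene_test(list(a = 1:3, b = 2)), "2 observations")
})

test_that("one-way ANOVA F and degrees of freedom match the SS oracle", {
  # 4 treatments x 3 replicate days, the field design
  set.seed(12)
  g4 <- list(kg16 = rnorm(3, 10), kg21 = rnorm(3, 14),
             kg25 = rnorm(3, 9), nobox = rnorm(3, 8))
  at <- anova_tukey(g4)
  expect_equal(at$df_between, 3L)
  expect_equal(at$df_within, 8L)
  expect_equal(at$F, oracle_anova_F(g4), tolerance = 1e-12)

  # identical groups: F = 0 and a single shared letter
  flat <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  atf <- anova_tukey(flat)
  expect_equal(atf$F, 0)
  expect_equal(length(unique(atf$means$letter)), 1L)

  # textbook 3-group case against the oracle, including invariances
  g3 <- list(a = c(5, 7, 6, 8), b = c(9, 11, 10, 13), c = c(5, 6, 5, 7))
  expect_equal(anova_tukey(g3)$F, oracle_anova_F(g3), tolerance = 1e-12)
  shift <- lapply(g3, `+`, 100)
  scaled <- lapply(g3, `*`, 3.7)
  expect_equal(anova_tukey(shift)$F, anova_tukey(g3)$F, tolerance = 1e-9)
  expect_equal(anova_tukey(scaled)$F, anova_tukey(g3)$F, tolerance = 1e-9)
})

test_that("Tukey-Kramer letters respect the pairwise significance matrix", {
  set.seed(21)
  g <- list(lo = rnorm(6, 0, 0.5), mid = rnorm(6, 1, 0.5),
            hi = rnorm(6, 8, 0.5), hi2 = rnorm(6, 8.2, 0.5))
  at <- anova_tukey(g)
  letters_of <- stats::setNames(at$means$letter, at$means$group)
  share <- function(a, b)
    length(intersect(strsplit(letters_of[[a]], "")[[1]],
                     strsplit(letters_of[[b]], "")[[1]])) > 0
  for (r in seq_len(nrow(at$pairs))) {
    ab <- strsplit(at$pairs$pair[r], "-", fixed = TRUE)[[1]]
    if (at$pairs$significant[r]) {
      expect_false(share(ab[1], ab[2]), info = at$pairs$pair[r])
    } else {
      expect_true(share(ab[1], ab[2]), info = at$pairs$pair[r])
    }
  }
  # Tukey-adjusted p-values agree with stats::TukeyHSD by construction;
  # cross-check one pair against the studentised range distribution
  vals <- unlist(g)
  grp <- factor(rep(names(g), lengths(g)))
  mse <- sum(unlist(lapply(g, function(x) (x - mean(x))^2))) /
    (length(vals) - 4)
  q_obs <- abs(mean(g$mid) - mean(g$lo)) /
    sqrt(mse / 2 * (1 / 6 + 1 / 6))
  p_hand <- stats::ptukey(q_obs, 4, length(vals) - 4, lower.tail = FALSE)
  p_pkg <- at$pairs$p_adj[at$pairs$pair %in% c("mid-lo", "lo-mid")]
  expect_equal(p_pkg, p_hand, tolerance = 1e-8)
})

test_that("the field report summarises simulated treatments end to end", {
  sc <- simulate_dataset(seed = 3)
  fs <- field_stats_report(sc$series)
  expect_setequal(unique(fs$daily$treatment_id), names(sc$series))
  expect_equal(nrow(fs$daily), 4 * 11)
  expect_true(all(fs$daily$minutes_above_threshold >= 0))
  expect_true(all(fs$daily$degree_minutes >= 0))
  # dm = 0 wherever time-above = 0 (shared base)
  expect_true(all(fs$daily$degree_minutes[
    fs$daily$minutes_above_threshold == 0] == 0))
  expect_equal(fs$time_above$anova$df_between, 3L)
  expect_equal(fs$time_above$anova$df_within, 40L)
  expect_true(fs$degree_minutes$anova$p >= 0 &&
                fs$degree_minutes$anova$p <= 1)
})
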