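test_that("episode segmentation finds maximal above-threshold runs", {
  cfg <- labeling_config()

  expect_length(segment_episodes(make_series(c(30, 35, 39.9)), cfg), 0L)

  eps <- segment_episodes(make_series(c(41, 45, 50, 40)), cfg)
  expect_length(eps, 1L)
  expect_equal(eps[[1]]$start, 1L)
  expect_equal(eps[[1]]$end, 4L)

  eps <- segment_episodes(make_series(c(38, 41, 42, 39, 45)), cfg)
  expect_length(eps, 2L)
  expect_equal(eps[[1]]$start, 2L)
  expect_equal(eps[[1]]$end, 3L)
  expect_equal(eps[[1]]$minutes_per_bin, c("41" = 15, "42" = 15))
  expect_equal(eps[[2]]$start, 5L)
  expect_equal(eps[[2]]$minutes_per_bin, c("45" = 15))

  # bin minutes always sum to episode duration and keys stay >= threshold
  for (e in eps) {
    expect_equal(sum(e$minutes_per_bin),
                 (e$end - e$start + 1L) * cfg$cadence)
    expect_true(all(as.numeric(names(e$minutes_per_bin)) >= cfg$threshold))
  }
})

test_that("series validation names the offending index", {
  tm <- t0 + c(0, 900, 1800, 2000)
  expect_error(temperature_series(tm, c(41, 41, 41, 41)),
               "index 4")
  expect_error(temperature_series(t0 + c(0, 900, 900), c(40, 40, 40)),
               "index 3")
  expect_error(temperature_series(t0 + c(0, 900), c(40, NA)),
               "index 2")
})

test_that("required exposure halves per degree above the threshold", {
  cfg <- labeling_config()
  expect_equal(required_minutes(40, cfg), 1440)
  expect_equal(required_minutes(45, cfg), 45)
  expect_equal(required_minutes(50, cfg), 1.40625)
  expect_equal(required_minutes(41:49, cfg) / required_minutes(42:50, cfg),
               rep(2, 9))
  expect_error(required_minutes(39.5, cfg), "below threshold")
})

test_that("amortised score matches hand arithmetic and floors correctly", {
  cfg <- labeling_config()
  ep <- function(bins) structure(list(minutes_per_bin = bins),
                                 class = "episode")
  s <- amortised_score(ep(c("40" = 1440)), cfg)
  expect_identical(s$raw, 1)
  expect_identical(s$s_hat, 1L)
  expect_true(s$effective)

  s <- amortised_score(ep(c("45" = 45)), cfg)
  expect_equal(s$raw, 1)
  expect_true(s$effective)

  s <- amortised_score(ep(c("45" = 30)), cfg)
  expect_equal(s$raw, 30 / 45)
  expect_identical(s$s_hat, 0L)
  expect_false(s$effective)

  s <- amortised_score(NULL, cfg)
  expect_identical(s$raw, 0)
  expect_false(s$effective)

  expect_error(amortised_score(ep(c("39" = 15)), cfg), "below threshold")
})

test_that("per-reading labels follow running and end-of-episode semantics", {
  run <- labeling_config(mode = "running")
  eoe <- labeling_config(mode = "end_of_episode")

  cold <- make_series(rep(35, 10))
  expect_equal(label_series(cold, run)$frame$label, rep(0L, 10))

  hot3 <- make_series(c(45, 45, 45))
  expect_equal(label_series(hot3, run)$frame$label, c(0L, 0L, 1L))
  expect_equal(label_series(hot3, eoe)$frame$label, c(1L, 1L, 1L))

  # below-threshold readings always 0; scores reset across episodes
  mix <- make_series(c(45, 45, 45, 39, 45, 45))
  lf <- label_series(mix, run)$frame
  expect_equal(lf$label, c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(lf$raw_score[4], 0)
  expect_equal(lf$episode[4], NA_integer_)
  expect_equal(lf$episode[5:6], c(2L, 2L))
})

test_that("scores agree with the per-minute brute-force oracle", {
  cfg <- labeling_config()
  set.seed(101)
  for (rep in 1:200) {
    temps <- round(runif(sample(5:40, 1), 30, 50), 2)
    ser <- make_series(temps)
    got <- vapply(segment_episodes(ser, cfg),
                  function(e) amortised_score(e, cfg)$raw, 1)
    expect_equal(got, oracle_raw_scores(temps), tolerance = 1e-9)
  }
})

test_that("score is monotone in duration and temperature, and resets hurt", {
  cfg <- labeling_config()
  set.seed(77)
  for (rep in 1:25) {
    temps <- runif(12, 40, 48)
    base <- oracle_raw_scores(temps)

    # appending an above-threshold reading never decreases raw
    expect_gte(oracle_raw_scores(c(temps, 41))[1], base[1])

    # raising one reading never decreases raw
    i <- sample(12, 1)
    up <- temps; up[i] <- up[i] + runif(1, 0, 3)
    expect_gte(oracle_raw_scores(up)[1], base[1])

    # splitting a run with a cold reading gives two episodes, each <= merged
    cut <- sample(2:11, 1)
    split <- c(temps[1:(cut - 1)], 30, temps[cut:12])
    parts <- oracle_raw_scores(split)
    expect_length(parts, 2L)
    expect_true(all(parts <= base[1] + 1e-12))

    # and the package agrees with the oracle on all three variants
    for (v in list(c(temps, 41), up, split)) {
      ser <- make_series(v)
      got <- vapply(segment_episodes(ser, cfg),
                    function(e) amortised_score(e, cfg)$raw, 1)
      expect_equal(got, oracle_raw_scores(v), tolerance = 1e-9)
    }
  }
})

test_that("doubling law: m minutes at T+1 equals 2m minutes at T", {
  cfg <- labeling_config()
  ep <- function(bins) structure(list(minutes_per_bin = bins),
                                 class = "episode")
  for (m in c(15, 45, 90, 720)) {
    lo <- amortised_score(ep(stats::setNames(2 * m, "40")), cfg)$raw
    hi <- amortised_score(ep(stats::setNames(m, "41")), cfg)$raw
    expect_identical(lo, hi)
  }
  # and across higher levels
  expect_identical(
    amortised_score(ep(c("44" = 30)), cfg)$raw,
    amortised_score(ep(c("43" = 60)), cfg)$raw)
})

test_that("thermocouple logs round-trip through labelling CSV output", {
  tmp_in <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".csv")
  tm <- t0 + 900 * (0:5)
  df <- data.frame(
    timestamp = format(rep(tm, 2), "%Y-%m-%dT%H:%M:%S"),
    position = "bottom",
    temperature_C = c(38, 45, 45, 45, 39, 40, rep(30, 6)),
    treatment_id = rep(c("kg21_box", "kg25_box"), each = 6))
  utils::write.csv(df, tmp_in, row.names = FALSE)

  log <- read_temperature_log(tmp_in)
  out <- label_log(log, labeling_config(), path = tmp_out)
  back <- utils::read.csv(tmp_out)
  expect_equal(names(back),
               c(names(df), "raw_score", "s_hat", "label"))
  expect_equal(back$label[back$treatment_id == "kg21_box"],
               c(0, 0, 0, 1, 0, 0))
  expect_equal(sum(back$label[back$treatment_id == "kg25_box"]), 0)
})
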