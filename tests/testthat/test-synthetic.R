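test_that("weather generator honours degenerate and deterministic contracts", {
  cfg0 <- weather_config(n_days = 2, ambient_amplitude = 0,
                         ambient_noise_sd = 0, day_sd = 0,
                         heatwave_amp = 0, rain_prob = 0)
  wx <- simulate_weather(cfg0, seed = 1)
  expect_equal(diff(range(wx$ambient_temp_C)), 0)

  w1 <- simulate_weather(weather_config(n_days = 3), seed = 42)
  w2 <- simulate_weather(weather_config(n_days = 3), seed = 42)
  expect_identical(w1, w2)
  w3 <- simulate_weather(weather_config(n_days = 3), seed = 43)
  expect_false(identical(w1$ambient_temp_C, w3$ambient_temp_C))

  wx <- simulate_weather(weather_config(n_days = 6), seed = 7)
  expect_true(all(wx$air_rh_pct >= 0 & wx$air_rh_pct <= 100))
  expect_true(all(wx$solar_radiation_MJ_m2 >= 0))
  expect_true(all(wx$solar_flux_KJ_m2 >= 0))
  expect_true(all(wx$wind_direction_deg >= 0 & wx$wind_direction_deg < 360))
  # night-time solar is dark
  expect_true(all(wx$solar_flux_KJ_m2[wx$hour < 5 | wx$hour > 19] == 0))

  expect_error(weather_config(cadence = 0), "cadence")
  expect_error(weather_config(rain_prob = 1.5), "rain_prob")
})

test_that("treatment specs enforce the four field treatments", {
  expect_equal(treatment_spec(16)$treatment_id, "kg16_box")
  expect_equal(treatment_spec(21, in_box = FALSE)$treatment_id,
               "kg21_no_box")
  expect_error(treatment_spec(18), "16, 21, 25")
  expect_error(treatment_spec(25, in_box = FALSE), "21-kg")
  ids <- vapply(default_treatments(), `[[`, "", "treatment_id")
  expect_setequal(ids, c("kg16_box", "kg21_box", "kg25_box", "kg21_no_box"))
})

test_that("bag response relaxes to ambient and slows with thermal mass", {
  wx <- simulate_weather(weather_config(n_days = 3), seed = 11)
  tr <- treatment_spec(21)

  set.seed(1)
  calm <- simulate_bag_temperature(
    wx, tr, bag_thermal_params(0, 60, mixing_boost = 0,
                               disturbance_sd = 0))
  gap <- abs(calm$temperature - wx$ambient_temp_C)
  # after a transient the bag tracks ambient within the diurnal lag band
  expect_lt(max(gap[-(1:24)]), max(gap) + 1e-9)
  expect_lt(mean(gap[-(1:24)]), 4)

  p_fast <- bag_thermal_params(0.015, 60, disturbance_sd = 0)
  p_slow <- bag_thermal_params(0.015, 120, disturbance_sd = 0)
  set.seed(2); fast <- simulate_bag_temperature(wx, tr, p_fast)
  set.seed(2); slow <- simulate_bag_temperature(wx, tr, p_slow)
  expect_lt(max(slow$temperature), max(fast$temperature))

  expect_error(
    simulate_bag_temperature(wx, tr, bag_thermal_params(0.01, 7)),
    "stable")
})

test_that("default calibration ranks daily heat with an interior maximum in mass", {
  ok <- 0L
  for (sd in 1:5) {
    sc <- simulate_dataset(seed = sd)
    mins <- vapply(sc$series, function(s) 15 * sum(s$temperature > 40), 1)
    ok <- ok + as.integer(
      mins["kg21_box"] > mins["kg16_box"] &&
        mins["kg16_box"] > mins["kg25_box"] &&
        mins["kg21_box"] > mins["kg21_no_box"])
  }
  expect_gte(ok, 4L)
})

test_that("feature table has the deposited schema and one-hot invariant", {
  sc <- simulate_dataset(seed = 2, weather = weather_config(n_days = 1),
                         mixing_days = 1)
  expect_equal(nrow(sc$table), 384L)  # 96 readings x 4 treatments
  expect_named(sc$table, feature_columns())
  onehot <- with(sc$table, kg16_box + kg21_box + kg25_box + kg21_no_box)
  expect_true(all(onehot == 1))
  expect_true(all(sc$table$class_label %in% c(0, 1)))

  # all-cold weather gives an all-negative label column
  cold <- simulate_dataset(seed = 3,
                           weather = weather_config(n_days = 2,
                                                    ambient_mean = 5))
  expect_equal(sum(cold$table$class_label), 0)

  # misaligned labels are refused
  wx <- sc$weather
  bad <- sc$labels
  bad[[1]]$frame <- bad[[1]]$frame[-1, ]
  expect_error(build_feature_table(wx, bad), "align")
})

test_that("prevalence responds monotonically to the ambient-mean knob", {
  cool <- simulate_dataset(seed = 4,
                           weather = weather_config(ambient_mean = 19))
  warm <- simulate_dataset(seed = 4,
                           weather = weather_config(ambient_mean = 24))
  expect_gte(warm$prevalence, cool$prevalence)
})

test_that("scenario generation is reproducible under its seed", {
  a <- simulate_dataset(seed = 9)
  b <- simulate_dataset(seed = 9)
  expect_identical(a$table, b$table)
  expect_identical(a$series$kg21_box$temperature,
                   b$series$kg21_box$temperature)
})
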