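#' Weather-scenario configuration
#'
#' Parameters of the synthetic weather generator that emulates the
#' weather-station record of a Canadian-summer field season: a diurnal
#' ambient-temperature sinusoid with day-to-day variation and Gaussian
#' noise, relative humidity anti-correlated with temperature, bell-shaped
#' daytime solar radiation and flux (attenuated on rain days), wind,
#' wind direction and air pressure as nuisance processes.
#'
#' Defaults describe late-July/August southern-Canada conditions: mean
#' 21.5 degrees C with 8 degrees diurnal amplitude puts typical daily
#' maxima near 30 degrees C, and a deterministic mid-season warm spell
#' (+3.5 degrees at its centre) plus N(0, 1.2) day-to-day noise puts the
#' hottest days in the low-to-mid 30s, matching the 28-32 degree maxima
#' of the field season the generator emulates.
#'
#' @param n_days Number of simulated days (default 11: a 5-day
#'   mixing/stacking part followed by a 6-day undisturbed part).
#' @param cadence Sampling interval in minutes (default 15).
#' @param ambient_mean,ambient_amplitude Mean and diurnal semi-amplitude of
#'   ambient temperature, degrees C.
#' @param ambient_noise_sd Within-day Gaussian noise s.d., degrees C.
#' @param day_sd S.d. of the random per-day temperature offset, degrees C.
#' @param heatwave_amp Peak of a deterministic warm spell (degrees C added
#'   to the day offset) centred on `heatwave_day` with Gaussian width
#'   `heatwave_width` days — the synoptic-scale hot days on which the bags
#'   can reach lethal temperatures.
#' @param heatwave_day,heatwave_width Centre (day number) and width (days)
#'   of the warm spell.
#' @param rh_mean,rh_amplitude Mean and swing of air relative humidity (%),
#'   clamped to \[0, 100\].
#' @param solar_peak Clear-sky peak of the solar-radiation channel
#'   (deposited-table units, MJ/m^2).
#' @param flux_peak Clear-sky peak solar flux density (KJ/m^2).
#' @param wind_mean Mean wind speed, m/s.
#' @param pressure_mean Mean air pressure, kPa.
#' @param rain_prob Probability that a day is a rain day; rain attenuates
#'   the solar channels and sets the binary rain flag.
#' @param start Start timestamp (POSIXct or ISO string, UTC).
#' @return An object of class `weather_config`.
#' @export
weather_config <- function(n_days = 11, cadence = 15, ambient_mean = 21.5,
                           ambient_amplitude = 8, ambient_noise_sd = 0.6,
                           day_sd = 1.2, heatwave_amp = 3.5,
                           heatwave_day = 7, heatwave_width = 2.5,
                           rh_mean = 62, rh_amplitude = 14,
                           solar_peak = 150, flux_peak = 800,
                           wind_mean = 2.5, pressure_mean = 99.5,
                           rain_prob = 0.15,
                           start = "2018-07-26 00:00:00") {
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  if (cadence <= 0) stop("`cadence` must be positive", call. = FALSE)
  if (ambient_amplitude < 0 || rh_amplitude < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  if (rain_prob < 0 || rain_prob > 1)
    stop("`rain_prob` must be in [0, 1]", call. = FALSE)
  structure(list(n_days = as.integer(n_days), cadence = cadence,
                 ambient_mean = ambient_mean,
                 ambient_amplitude = ambient_amplitude,
                 ambient_noise_sd = ambient_noise_sd, day_sd = day_sd,
                 heatwave_amp = heatwave_amp, heatwave_day = heatwave_day,
                 heatwave_width = heatwave_width,
                 rh_mean = rh_mean, rh_amplitude = rh_amplitude,
                 solar_peak = solar_peak, flux_peak = flux_peak,
                 wind_mean = wind_mean, pressure_mean = pressure_mean,
                 rain_prob = rain_prob,
                 start = as.POSIXct(start, tz = "UTC")),
            class = "weather_config")
}

#' Simulate a weather-station record
#'
#' @param config A [weather_config()].
#' @param seed Optional RNG seed; identical seeds give identical series.
#' @return A data frame with columns `time`, `day`, `hour`,
#'   `ambient_temp_C`, `air_rh_pct`, `solar_radiation_MJ_m2`,
#'   `solar_flux_KJ_m2`, `wind_speed_m_s`, `wind_direction_deg`,
#'   `air_pressure_kPa`, `rain`.
#' @export
simulate_weather <- function(config = weather_config(), seed = NULL) {
  stopifnot(inherits(config, "weather_config"))
  if (!is.null(seed)) set.seed(seed)
  per_day <- as.integer(round(1440 / config$cadence))
  n <- config$n_days * per_day
  time <- config$start + 60 * config$cadence * (seq_len(n) - 1L)
  day <- rep(seq_len(config$n_days), each = per_day)
  hour <- (as.numeric(time - config$start, units = "mins") / 60) %% 24

  warm_spell <- config$heatwave_amp *
    exp(-((seq_len(config$n_days) - config$heatwave_day) /
            config$heatwave_width)^2)
  day_offset <- warm_spell + stats::rnorm(config$n_days, 0, config$day_sd)
  rain_day <- stats::runif(config$n_days) < config$rain_prob
  # diurnal sinusoid peaking mid-afternoon (15:00)
  diurnal <- sin(2 * pi * (hour - 9) / 24)
  ambient <- config$ambient_mean + config$ambient_amplitude * diurnal +
    day_offset[day] - 2 * rain_day[day] +
    stats::rnorm(n, 0, config$ambient_noise_sd)

  # solar elevation proxy: zero at night, bell between 06:00 and 18:00
  elev <- pmax(0, sin(pi * (hour - 6) / 12))
  atten <- ifelse(rain_day[day], 0.25, 1) *
    (0.92 + 0.08 * stats::runif(config$n_days))[day]
  solar <- config$solar_peak * elev^1.4 * atten *
    pmax(0, 1 + stats::rnorm(n, 0, 0.05))
  flux <- config$flux_peak * elev^1.2 * atten *
    pmax(0, 1 + stats::rnorm(n, 0, 0.05))

  rh <- config$rh_mean -
    config$rh_amplitude * (ambient - config$ambient_mean) /
      max(config$ambient_amplitude, 1) +
    12 * rain_day[day] + stats::rnorm(n, 0, 6)
  rh <- pmin(100, pmax(0, rh))

  wind <- pmax(0, config$wind_mean * (0.4 + 0.6 * stats::rgamma(n, 2, 2)))
  # prevailing direction with mean-reverting (AR(1)) wander
  prevailing <- stats::runif(1, 0, 360)
  wobble <- stats::filter(stats::rnorm(n, 0, 12), 0.8, method = "recursive")
  wdir <- (prevailing + as.numeric(wobble)) %% 360
  # calm anticyclonic pressure: weak diurnal tide plus instrument noise
  pressure <- config$pressure_mean + 0.1 * sin(2 * pi * (hour - 4) / 24) +
    stats::rnorm(n, 0, 0.05)

  data.frame(time = time, day = day, hour = hour,
             ambient_temp_C = ambient, air_rh_pct = rh,
             solar_radiation_MJ_m2 = solar, solar_flux_KJ_m2 = flux,
             wind_speed_m_s = wind, wind_direction_deg = wdir,
             air_pressure_kPa = pressure,
             rain = as.integer(rain_day[day]))
}

#' Specify a bag treatment
#'
#' The field protocol compared four treatments: 16, 21 and 25 kg of wheat
#' in clear polyethylene bags inside wooden boxes, and 21 kg without a box.
#'
#' @param mass_kg Grain mass, one of 16, 21, 25.
#' @param in_box Whether the bag sits in a wooden box. Only the 21-kg
#'   treatment is defined without a box.
#' @param mixing_stacking Default mixing/stacking flag (the first field
#'   part mixed and stacked the bags overnight); usually supplied per day
#'   via `mixing_days` in [simulate_dataset()].
#' @return An object of class `treatment_spec` with a derived
#'   `treatment_id` (`kg16_box`, `kg21_box`, `kg25_box`, `kg21_no_box`).
#' @export
treatment_spec <- function(mass_kg, in_box = TRUE, mixing_stacking = FALSE) {
  if (!mass_kg %in% c(16, 21, 25))
    stop("`mass_kg` must be one of 16, 21, 25", call. = FALSE)
  if (!in_box && mass_kg != 21)
    stop("only the 21-kg treatment is defined without a box", call. = FALSE)
  id <- if (in_box) sprintf("kg%d_box", mass_kg) else "kg21_no_box"
  structure(list(mass_kg = mass_kg, in_box = in_box,
                 mixing_stacking = mixing_stacking, treatment_id = id),
            class = "treatment_spec")
}

#' The four field treatments
#' @return List of four [treatment_spec()] objects.
#' @export
default_treatments <- function() {
  list(treatment_spec(16, TRUE), treatment_spec(21, TRUE),
       treatment_spec(25, TRUE), treatment_spec(21, FALSE))
}

#' Lumped thermal parameters of a bag bottom
#'
#' The field study developed no physical heat-transfer model; this package
#' therefore uses the simplest forcing model with a mass-dependent lag: a
#' first-order response of the bag-bottom temperature towards an
#' equilibrium set by ambient temperature plus a solar gain, integrated at
#' the logger cadence.
#'
#' @param solar_gain Equilibrium excess temperature per unit solar flux
#'   (degrees C per KJ/m^2).
#' @param time_constant Thermal lag in minutes; grows with grain mass.
#' @param loss_rate Night-time cooling modifier (>= 1): the effective lag
#'   at night is `time_constant / loss_rate`, so un-boxed bags (larger
#'   `loss_rate`) shed heat faster.
#' @param mixing_boost Additive equilibrium offset (degrees C) applied when
#'   the mixing/stacking flag is on.
#' @param disturbance_sd Stationary s.d. (degrees C) of a slowly varying
#'   AR(1) disturbance on the equilibrium temperature, standing in for
#'   unobserved bag state (partial shading, condensation, substrate
#'   contact) that the weather record cannot see. Because the lethality
#'   score doubles per degree, this disturbance makes borderline days
#'   genuinely unpredictable from the observed features — the source of
#'   the irreducible minority-class error on the imbalanced dataset.
#' @return An object of class `bag_thermal_params`.
#' @export
bag_thermal_params <- function(solar_gain, time_constant, loss_rate = 1.2,
                               mixing_boost = 2, disturbance_sd = 1) {
  if (time_constant <= 0) stop("`time_constant` must be > 0", call. = FALSE)
  if (solar_gain < 0) stop("`solar_gain` must be >= 0", call. = FALSE)
  if (loss_rate < 1) stop("`loss_rate` must be >= 1", call. = FALSE)
  if (disturbance_sd < 0) stop("`disturbance_sd` must be >= 0", call. = FALSE)
  structure(list(solar_gain = solar_gain, time_constant = time_constant,
                 loss_rate = loss_rate, mixing_boost = mixing_boost,
                 disturbance_sd = disturbance_sd),
            class = "bag_thermal_params")
}

#' Default per-treatment thermal calibration
#'
#' Calibrated once so that the synthetic field season reproduces the
#' study's qualitative findings: the bag bottoms cross 40 degrees C only on
#' hot days, the 21-kg-in-box treatment accumulates the most time above
#' 40 degrees C (an interior maximum in grain mass: thin layers gain heat
#' fast but also lose it fast, thick layers never heat through), and the
#' un-boxed 21-kg bag, lacking the box's insulation, trails all boxed
#' treatments.
#'
#' @param treatment A [treatment_spec()].
#' @return A [bag_thermal_params()].
#' @export
default_bag_params <- function(treatment) {
  stopifnot(inherits(treatment, "treatment_spec"))
  switch(treatment$treatment_id,
    kg16_box = bag_thermal_params(0.0140, 55, loss_rate = 1.45,
                                  mixing_boost = 2),
    kg21_box = bag_thermal_params(0.0186, 75, loss_rate = 1.2,
                                  mixing_boost = 2),
    kg25_box = bag_thermal_params(0.0133, 100, loss_rate = 1.1,
                                  mixing_boost = 2),
    kg21_no_box = bag_thermal_params(0.0110, 70, loss_rate = 1.8,
                                     mixing_boost = 2))
}

#' Simulate the bag-bottom temperature response
#'
#' Integrates the first-order response `dT/dt = (T_eq - T)/tau` with
#' explicit Euler steps at the weather cadence, where
#' `T_eq = ambient + solar_gain * flux + mixing_boost * mixing + w`, `w`
#' is the unobserved AR(1) bag-state disturbance, and the effective `tau`
#' is `time_constant` while the sun is up and `time_constant / loss_rate`
#' at night. Uses the current RNG stream (seed it upstream for
#' reproducibility).
#'
#' @param weather A weather record from [simulate_weather()].
#' @param treatment A [treatment_spec()].
#' @param params A [bag_thermal_params()]; defaults to the calibrated
#'   per-treatment values.
#' @param mixing Logical vector (length 1 or `nrow(weather)`) of
#'   mixing/stacking flags; defaults to the treatment's flag.
#' @return A [temperature_series()] for the bag-bottom position.
#' @export
simulate_bag_temperature <- function(weather, treatment,
                                     params = default_bag_params(treatment),
                                     mixing = NULL) {
  stopifnot(inherits(treatment, "treatment_spec"),
            inherits(params, "bag_thermal_params"))
  n <- nrow(weather)
  cadence <- as.numeric(diff(weather$time[1:2]), units = "mins")
  if (params$time_constant <= cadence / 2)
    stop("`time_constant` (", params$time_constant,
         " min) too small for stable Euler integration at cadence ",
         cadence, " min", call. = FALSE)
  if (is.null(mixing)) mixing <- treatment$mixing_stacking
  mixing <- rep_len(as.numeric(mixing), n)
  # unobserved bag-state disturbance: AR(1) with ~6 h decay at 15-min steps
  phi <- 0.97^(cadence / 15)
  w <- as.numeric(stats::filter(
    stats::rnorm(n, 0, params$disturbance_sd * sqrt(1 - phi^2)),
    phi, method = "recursive"))
  t_eq <- weather$ambient_temp_C + params$solar_gain * weather$solar_flux_KJ_m2 +
    params$mixing_boost * mixing + w
  tau <- ifelse(weather$solar_flux_KJ_m2 > 0, params$time_constant,
                params$time_constant / params$loss_rate)
  temp <- numeric(n)
  temp[1] <- weather$ambient_temp_C[1]
  for (i in 2:n)
    temp[i] <- temp[i - 1] +
      cadence * (t_eq[i - 1] - temp[i - 1]) / tau[i - 1]
  temperature_series(weather$time, temp, position = "bottom",
                     treatment_id = treatment$treatment_id)
}

#' Feature-table column order
#'
#' The 14 columns of the observation table: 13 predictors plus the binary
#' class label.
#' @return Character vector of column names.
#' @export
feature_columns <- function() {
  c("kg16_box", "air_rh_pct", "ambient_temp_C", "kg21_no_box",
    "solar_radiation_MJ_m2", "solar_flux_KJ_m2", "wind_speed_m_s",
    "mixing_stacking", "air_pressure_kPa", "kg21_box",
    "wind_direction_deg", "kg25_box", "rain", "class_label")
}

#' Assemble the observation table
#'
#' One row per timestamp and treatment: the shared weather features, the
#' one-hot treatment flags, the mixing/stacking and rain flags, and the
#' class label copied from the labelling engine applied to the treatment's
#' bag-bottom series.
#'
#' @param weather A weather record from [simulate_weather()].
#' @param labelled A named list (by treatment id) of `series_labels` from
#'   [label_series()], time-aligned with `weather`.
#' @param mixing Logical vector (length 1 or `nrow(weather)`) of
#'   mixing/stacking flags shared by all treatments.
#' @return A data frame with the 14 [feature_columns()] plus a `time`
#'   attribute column set aside as `attr(, "time")`.
#' @export
build_feature_table <- function(weather, labelled, mixing = FALSE) {
  ids <- c("kg16_box", "kg21_box", "kg25_box", "kg21_no_box")
  miss <- setdiff(names(labelled), ids)
  if (length(miss))
    stop("unknown treatment id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mixing <- rep_len(as.integer(mixing), nrow(weather))
  parts <- lapply(names(labelled), function(id) {
    lf <- labelled[[id]]$frame
    if (nrow(lf) != nrow(weather) ||
        any(abs(as.numeric(lf$time) - as.numeric(weather$time)) > 1e-6))
      stop("timestamps of labelled series `", id,
           "` do not align with the weather record", call. = FALSE)
    df <- data.frame(
      kg16_box = as.integer(id == "kg16_box"),
      air_rh_pct = weather$air_rh_pct,
      ambient_temp_C = weather$ambient_temp_C,
      kg21_no_box = as.integer(id == "kg21_no_box"),
      solar_radiation_MJ_m2 = weather$solar_radiation_MJ_m2,
      solar_flux_KJ_m2 = weather$solar_flux_KJ_m2,
      wind_speed_m_s = weather$wind_speed_m_s,
      mixing_stacking = mixing,
      air_pressure_kPa = weather$air_pressure_kPa,
      kg21_box = as.integer(id == "kg21_box"),
      wind_direction_deg = weather$wind_direction_deg,
      kg25_box = as.integer(id == "kg25_box"),
      rain = weather$rain,
      class_label = lf$label)
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate the full default field scenario
#'
#' End-to-end synthetic dataset: weather, the four treatments' bag-bottom
#' series (mixing/stacking on the first `mixing_days` days, as in the
#' first field part), episode labelling of every bottom series, and the
#' assembled 14-column observation table. Under the defaults (11 days,
#' 15-min cadence, 4 treatments) the table has 4224 rows and a positive
#' prevalence of roughly 1-2%, the severe imbalance the downstream
#' experiments are designed around.
#'
#' @param seed RNG seed (drives every stochastic component).
#' @param weather A [weather_config()].
#' @param labeling A [labeling_config()].
#' @param treatments List of [treatment_spec()]s.
#' @param mixing_days Integer vector of day numbers with mixing/stacking.
#' @param params_fn Function mapping a treatment to its
#'   [bag_thermal_params()].
#' @return A list of class `solar_scenario`: `weather`, `series` (named
#'   list of temperature series), `labels` (named list of `series_labels`),
#'   `table` (the feature table) and `prevalence`.
#' @export
simulate_dataset <- function(seed = 1, weather = weather_config(),
                             labeling = labeling_config(),
                             treatments = default_treatments(),
                             mixing_days = 1:5,
                             params_fn = default_bag_params) {
  wx <- simulate_weather(weather, seed = seed)
  mixing <- wx$day %in% mixing_days
  series <- list()
  labels <- list()
  for (tr in treatments) {
    ser <- simulate_bag_temperature(wx, tr, params_fn(tr), mixing = mixing)
    series[[tr$treatment_id]] <- ser
    labels[[tr$treatment_id]] <- label_series(ser, labeling)
  }
  tab <- build_feature_table(wx, labels, mixing = mixing)
  structure(list(weather = wx, series = series, labels = labels,
                 table = tab, prevalence = mean(tab$class_label)),
            class = "solar_scenario")
}

#' Write/read a feature table as CSV with a schema sidecar
#'
#' @param table A feature table.
#' @param path CSV path; the sidecar is written to `paste0(path, ".schema.json")`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  schema <- list(columns = names(table),
                 types = vapply(table, function(x) class(x)[1], ""),
                 n_rows = nrow(table))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
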