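#' Labelling configuration for the amortised lethality score
#'
#' Bundles the parameters of the episode-labelling engine: the lethal
#' temperature threshold, the day length used as the exposure normaliser,
#' the width of the temperature bins that discretise continuous readings,
#' the sampling cadence of the logger, and the labelling mode.
#'
#' The score of an above-threshold episode is
#' \deqn{S = \sum_{t \ge T} \frac{g_t}{D \, 2^{-(t-T)}},}
#' where \eqn{g_t} is the accumulated minutes at binned temperature level
#' \eqn{t}, \eqn{T} the threshold and \eqn{D} the minutes-per-day
#' normaliser: a full day at the threshold scores 1, and every additional
#' degree halves the required exposure. The floored score \eqn{\hat S} is
#' the effectiveness label (\eqn{\hat S \ge 1} means effective).
#'
#' @param threshold Lethal temperature threshold \eqn{T} in degrees C
#'   (default 40, the lower lethal limit for rice weevil adults).
#' @param day_minutes Normaliser \eqn{D} in minutes (default 1440, one day).
#' @param bin_width Temperature bin width in degrees C (default 1). Readings
#'   are binned to `threshold + floor((temp - threshold)/bin_width) *
#'   bin_width`, i.e. rounded *down*, which never overstates lethal exposure.
#' @param cadence Sampling interval of the logger in minutes (default 15).
#' @param mode `"running"` labels a reading 1 as soon as the cumulative
#'   episode score reaches 1; `"end_of_episode"` labels every reading of an
#'   episode whose final floored score is at least 1.
#' @return An object of class `labeling_config`.
#' @examples
#' cfg <- labeling_config()
#' required_minutes(45, cfg)  # 45 minutes suffice at 45 degrees C
#' @export
labeling_config <- function(threshold = 40, day_minutes = 1440, bin_width = 1,
                            cadence = 15, mode = c("running", "end_of_episode")) {
  mode <- match.arg(mode)
  for (nm in c("threshold", "day_minutes", "bin_width", "cadence")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  if (day_minutes != as.integer(day_minutes))
    stop("`day_minutes` must be an integer number of minutes", call. = FALSE)
  structure(list(threshold = threshold, day_minutes = day_minutes,
                 bin_width = bin_width, cadence = cadence, mode = mode),
            class = "labeling_config")
}

#' Construct a regularly sampled temperature series
#'
#' A temperature series is the reading stream of one thermocouple position
#' of one bag: strictly increasing timestamps at a constant cadence with
#' finite temperatures and no gaps.
#'
#' @param time `POSIXct` timestamps, strictly increasing, equally spaced.
#' @param temperature Temperatures in degrees C, same length as `time`.
#' @param position Sensor position label (the field protocol used six
#'   vertical positions; the bottom of the grain is the coldest and hence
#'   the conservative choice for labelling).
#' @param treatment_id Treatment identifier, e.g. `"kg21_box"`.
#' @return A data frame of class `temperature_series` with columns `time`
#'   and `temperature` and attributes `position`, `treatment_id`, `cadence`
#'   (minutes).
#' @export
temperature_series <- function(time, temperature, position = "bottom",
                               treatment_id = NA_character_) {
  if (!inherits(time, "POSIXct"))
    stop("`time` must be POSIXct", call. = FALSE)
  if (length(time) != length(temperature))
    stop("`time` and `temperature` lengths differ", call. = FALSE)
  if (length(time) < 1L) stop("empty series", call. = FALSE)
  ser <- structure(
    data.frame(time = time, temperature = as.numeric(temperature)),
    position = position, treatment_id = treatment_id,
    class = c("temperature_series", "data.frame"))
  attr(ser, "cadence") <- validate_series(ser)
  ser
}

#' Validate a temperature series
#'
#' Checks strict monotonicity and constant spacing of the timestamps and
#' finiteness of the temperatures; errors name the first offending index.
#'
#' @param series A `temperature_series` or a data frame with `time` and
#'   `temperature` columns.
#' @param cadence Optional expected cadence in minutes; when `NULL` the
#'   cadence is inferred from the first interval.
#' @return The cadence in minutes, invisibly usable.
#' @export
validate_series <- function(series, cadence = NULL) {
  tm <- series$time
  temp <- series$temperature
  if (is.null(tm) || is.null(temp))
    stop("series must have `time` and `temperature` columns", call. = FALSE)
  bad <- which(!is.finite(temp))
  if (length(bad))
    stop("non-finite temperature at index ", bad[1L], call. = FALSE)
  if (length(tm) > 1L) {
    dt <- as.numeric(diff(tm), units = "mins")
    if (is.null(cadence)) cadence <- dt[1L]
    bad <- which(abs(dt - cadence) > 1e-6 | dt <= 0)
    if (length(bad))
      stop("irregular cadence or non-monotone timestamp at index ",
           bad[1L] + 1L, " (interval ", signif(dt[bad[1L]], 6),
           " min, expected ", signif(cadence, 6), ")", call. = FALSE)
  } else if (is.null(cadence)) {
    cadence <- NA_real_
  }
  cadence
}

# Bin a temperature to its level key; guaranteed >= threshold for
# temperatures >= threshold because binning is anchored at the threshold.
bin_temperature <- function(temp, config) {
  config$threshold +
    floor((temp - config$threshold) / config$bin_width) * config$bin_width
}

#' Segment a series into above-threshold episodes
#'
#' An episode is a maximal contiguous run of readings at or above the
#' threshold; a single reading below the threshold ends the episode (the
#' score is reset, conservatively, whenever the temperature drops below the
#' threshold). Each reading contributes its full cadence of minutes to the
#' bin of its (floored) temperature.
#'
#' @inheritParams validate_series
#' @param config A [labeling_config()].
#' @return A list of `episode` objects, ordered by start index, each with
#'   fields `start`, `end` (1-based reading indices, inclusive) and
#'   `minutes_per_bin` (named numeric, names are bin temperatures).
#' @examples
#' tm <- as.POSIXct("2018-07-26 12:00", tz = "UTC") + 900 * (0:4)
#' s <- temperature_series(tm, c(38, 41, 42, 39, 45))
#' length(segment_episodes(s, labeling_config()))  # 2
#' @export
segment_episodes <- function(series, config = labeling_config()) {
  cad <- validate_series(series, cadence = NULL)
  if (is.na(cad)) cad <- config$cadence
  if (abs(cad - config$cadence) > 1e-6)
    stop("series cadence (", cad, " min) differs from config cadence (",
         config$cadence, " min)", call. = FALSE)
  temp <- series$temperature
  above <- temp >= config$threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    bins <- bin_temperature(temp[idx], config)
    g <- tapply(rep(config$cadence, length(idx)), bins, sum)
    out[[length(out) + 1L]] <- structure(
      list(start = starts[i], end = ends[i],
           minutes_per_bin = stats::setNames(as.numeric(g), names(g))),
      class = "episode")
  }
  out
}

#' Minutes of exposure required at a temperature level
#'
#' The exposure needed for an effective score of 1 halves with every degree
#' above the threshold: `day_minutes * 2^-(t - threshold)`. At the threshold
#' a full day is required; at threshold + 5 only 45 minutes.
#'
#' @param t Temperature level in degrees C, must be at or above the
#'   threshold.
#' @param config A [labeling_config()].
#' @return Required minutes (numeric, vectorised over `t`).
#' @export
required_minutes <- function(t, config = labeling_config()) {
  if (any(t < config$threshold))
    stop("temperature level below threshold (", config$threshold,
         " degrees C)", call. = FALSE)
  config$day_minutes * 2^(-(t - config$threshold))
}

#' Amortised lethality score of one episode
#'
#' Sums, over the episode's temperature bins, the accumulated minutes
#' divided by the level's required minutes; the floor of that sum is the
#' effectiveness label. An empty episode scores 0.
#'
#' @param episode An `episode` from [segment_episodes()] (or `NULL`/empty).
#' @param config A [labeling_config()].
#' @return An object of class `effectiveness_score`: list with `raw`
#'   (unfloored sum), `s_hat` (= `floor(raw)`) and `effective`
#'   (`s_hat >= 1`).
#' @export
amortised_score <- function(episode, config = labeling_config()) {
  if (is.null(episode) || length(episode$minutes_per_bin) == 0L) {
    return(structure(list(raw = 0, s_hat = 0L, effective = FALSE),
                     class = "effectiveness_score"))
  }
  g <- episode$minutes_per_bin
  lev <- as.numeric(names(g))
  if (any(lev < config$threshold - 1e-9))
    stop("episode bin key below threshold: ", min(lev), call. = FALSE)
  # raw = sum g_t / (D * 2^{-(t-T)}); accumulate the numerator first so the
  # single division by D keeps integer-minute inputs exact.
  raw <- sum(g * 2^(lev - config$threshold)) / config$day_minutes
  s_hat <- floor(raw)
  structure(list(raw = raw, s_hat = as.integer(s_hat),
                 effective = s_hat >= 1),
            class = "effectiveness_score")
}

#' Label every reading of a temperature series
#'
#' Applies the amortised score to each above-threshold episode and emits a
#' binary per-reading label. In `running` mode a reading is labelled 1 as
#' soon as the cumulative score of its episode (up to and including that
#' reading) reaches 1; in `end_of_episode` mode all readings of an episode
#' with final floored score >= 1 are labelled 1. Readings below the
#' threshold are always 0 and the score resets across episodes.
#'
#' @inheritParams segment_episodes
#' @return A list of class `series_labels`: `frame`, a data frame with
#'   columns `time`, `temperature`, `episode` (integer id or `NA`),
#'   `raw_score` (cumulative episode score at that reading, 0 below the
#'   threshold), `s_hat` (its floor) and `label` (0/1); and `episodes`, a
#'   list pairing each `episode` with its `effectiveness_score`.
#' @export
label_series <- function(series, config = labeling_config()) {
  eps <- segment_episodes(series, config)
  n <- nrow(series)
  lab <- integer(n)
  epi <- rep(NA_integer_, n)
  cum <- numeric(n)
  scored <- vector("list", length(eps))
  for (i in seq_along(eps)) {
    e <- eps[[i]]
    idx <- e$start:e$end
    bins <- bin_temperature(series$temperature[idx], config)
    cum_raw <- cumsum(config$cadence * 2^(bins - config$threshold)) /
      config$day_minutes
    sc <- amortised_score(e, config)
    epi[idx] <- i
    cum[idx] <- cum_raw
    lab[idx] <- if (config$mode == "running") as.integer(cum_raw >= 1)
                else rep(as.integer(sc$effective), length(idx))
    scored[[i]] <- list(episode = e, score = sc)
  }
  structure(list(
    frame = data.frame(time = series$time,
                       temperature = series$temperature,
                       episode = epi, raw_score = cum,
                       s_hat = floor(cum), label = lab),
    episodes = scored,
    position = attr(series, "position"),
    treatment_id = attr(series, "treatment_id")),
    class = "series_labels")
}

#' Read a thermocouple log from CSV
#'
#' Expects columns `timestamp` (ISO-8601), `position`, `temperature_C`,
#' `treatment_id`.
#'
#' @param path Path to the CSV file.
#' @param tz Time zone for parsing timestamps (default UTC).
#' @return A data frame with parsed `timestamp`.
#' @export
read_temperature_log <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "position", "temperature_C", "treatment_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("temperature log missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = tz,
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%d %H:%M"))
  if (anyNA(df$timestamp)) stop("unparseable timestamp in log", call. = FALSE)
  df
}

#' Label a thermocouple log and write the result as CSV
#'
#' Splits the log by treatment and position, labels each series, and writes
#' the log back with appended `raw_score`, `s_hat` and `label` columns.
#'
#' @param log A data frame as returned by [read_temperature_log()].
#' @param config A [labeling_config()].
#' @param path Optional output CSV path; when `NULL` nothing is written.
#' @return The labelled data frame (invisibly when `path` is given).
#' @export
label_log <- function(log, config = labeling_config(), path = NULL) {
  key <- interaction(log$treatment_id, log$position, drop = TRUE)
  parts <- lapply(split(log, key), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    ser <- temperature_series(d$timestamp, d$temperature_C,
                              position = d$position[1L],
                              treatment_id = d$treatment_id[1L])
    lb <- label_series(ser, config)$frame
    d$raw_score <- lb$raw_score
    d$s_hat <- lb$s_hat
    d$label <- lb$label
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- out[order(out$treatment_id, out$position, out$timestamp), ]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.effectiveness_score <- function(x, ...) {
  cat(sprintf("effectiveness score: raw = %.4f, s_hat = %d (%s)\n",
              x$raw, x$s_hat,
              if (x$effective) "effective" else "ineffective"))
  invisible(x)
}
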