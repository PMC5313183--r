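# Synthetic daily fire-weather archive. The synthetic calendar uses 365-day
# years (no Feb 29), so a +/-10-day window over a 20-year archive always
# holds exactly 21 * 20 candidate days.

.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_start <- cumsum(c(0L, .month_days[-12]))  # doy of day 0 of each month

.doy_to_md <- function(doy) {
  m <- findInterval(doy, .month_start + 1L)
  list(month = m, day = doy - .month_start[m])
}

#' Generate a synthetic daily weather archive
#'
#' One grid-constant record per day (the modelled region is small enough
#' that weather has no useful spatial gradient): sinusoidal seasonal mean
#' plus AR(1) noise for mean temperature; maximum temperature offset above
#' it; relative humidity anti-correlated with the temperature anomaly and
#' boosted on rain days; seasonal Bernoulli--Gamma precipitation placing
#' ~80% of rain in March--September; lognormal daily maximum wind speed and
#' uniform 16-sector wind direction. Consumes the current RNG stream (seed
#' with `set.seed()` or via [synth_config()]'s seed through the pipeline).
#'
#' @param config A [synth_config()].
#' @return A data frame of class `fire_weather`, one row per day:
#'   `date` (ISO string), `year`, `month`, `day`, `doy`, `t_max`, `t_avg`
#'   (degC), `rh` (%), `precip` (mm), `wind_dir` (1--16), `wind_max` (m/s).
#' @export
gen_weather <- function(config) {
  if (config$years < 1) stop("years must be >= 1")
  n <- config$years * 365L
  doy <- rep(1:365, config$years)
  year <- config$start_year + rep(seq_len(config$years) - 1L, each = 365L)
  seas <- config$t_mean + config$t_amp * sin(2 * pi * (doy - 105) / 365)
  innov_sd <- config$t_noise_sd * sqrt(1 - config$t_ar^2)
  anom <- as.numeric(
    stats::filter(stats::rnorm(n, 0, innov_sd), config$t_ar,
                  method = "recursive"))
  t_avg <- seas + anom
  t_max <- t_avg + config$tmax_offset + stats::rnorm(n, 0, config$tmax_sd)
  t_max <- pmax(t_max, t_avg)
  wet_season <- doy >= config$wet_doy[1] & doy <= config$wet_doy[2]
  p_rain <- ifelse(wet_season, config$p_wet, config$p_dry)
  rain <- stats::runif(n) < p_rain
  amt <- ifelse(wet_season, config$rain_mean_wet, config$rain_mean_dry)
  precip <- ifelse(rain,
                   stats::rgamma(n, shape = config$rain_shape,
                                 rate = config$rain_shape / amt), 0)
  rh <- config$rh_mean - config$rh_temp_coef * anom +
    config$rh_rain_boost * (rain - mean(p_rain)) +
    stats::rnorm(n, 0, config$rh_noise_sd)
  rh <- pmin(pmax(rh, 0), 100)
  wind_max <- stats::rlnorm(n, config$wind_meanlog, config$wind_sdlog)
  wind_dir <- sample.int(16L, n, replace = TRUE)
  md <- .doy_to_md(doy)
  out <- data.frame(
    date = sprintf("%04d-%02d-%02d", year, md$month, md$day),
    year = year, month = md$month, day = md$day, doy = doy,
    t_max = t_max, t_avg = t_avg, rh = rh, precip = precip,
    wind_dir = wind_dir, wind_max = wind_max,
    stringsAsFactors = FALSE)
  class(out) <- c("fire_weather", "data.frame")
  out
}

#' Validate a weather archive
#'
#' Checks the `WeatherDay` invariants: `t_max >= t_avg`, `rh` in \[0, 100\],
#' `precip >= 0`, integer `wind_dir` in 1..16, `wind_max >= 0`.
#'
#' @param weather A weather data frame.
#' @return `weather` invisibly; stops on the first violated invariant.
#' @export
validate_weather <- function(weather) {
  need <- c("doy", "t_max", "t_avg", "rh", "precip", "wind_dir", "wind_max")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather archive missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(weather$t_max < weather$t_avg)) stop("t_max < t_avg in archive")
  if (any(weather$rh < 0 | weather$rh > 100)) stop("rh outside [0, 100]")
  if (any(weather$precip < 0)) stop("negative precipitation")
  if (any(weather$wind_dir != round(weather$wind_dir) |
            weather$wind_dir < 1 | weather$wind_dir > 16))
    stop("wind_dir must be an integer sector in 1..16")
  if (any(weather$wind_max < 0)) stop("negative wind speed")
  invisible(weather)
}

#' Candidate archive rows for a day-of-year window
#'
#' All archive rows whose day-of-year lies within `half_width` days of
#' `doy`, circularly across the December/January boundary (so a window
#' around January 3 includes late-December days of every archive year).
#'
#' @param doy Day of year (1--365).
#' @param weather A weather archive.
#' @param half_width Window half-width in days.
#' @return Integer vector of archive row indices.
#' @export
weather_window <- function(doy, weather, half_width = 10L) {
  if (half_width < 0) stop("half_width must be >= 0")
  d <- abs(weather$doy - doy)
  which(pmin(d, 365L - d) <= half_width)
}

#' Draw the weather for one simulated fire day
#'
#' Uniform draw from all archive days whose day-of-year lies within
#' `half_width` days (circular) of the target day, i.e. from
#' `(2 * half_width + 1) * years` candidates.
#'
#' @inheritParams weather_window
#' @return One-row data frame (a `WeatherDay`).
#' @export
draw_weather <- function(doy, weather, half_width = 10L) {
  idx <- weather_window(doy, weather, half_width)
  if (!length(idx)) stop("empty weather-window candidate set for doy ", doy)
  weather[idx[sample.int(length(idx), 1L)], , drop = FALSE]
}
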