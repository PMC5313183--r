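#' Configuration for the synthetic fire world
#'
#' Bundles every knob of the synthetic-landscape generator together with the
#' *true* generative parameters (ignition log-odds coefficients, size-model
#' coefficients, monthly ignition rates, spread-rate coefficients) so that
#' parameter-recovery tests know the ground truth. Identical configurations
#' (including `seed`) reproduce byte-identical landscapes, weather archives
#' and fire histories.
#'
#' Defaults emulate a subtropical coniferous county with a strong
#' human-access gradient: a valley-following road and settlement system,
#' a fragmented four-type fuel mosaic (pine share declining above ~700 m),
#' a winter--spring fire season carrying ~85% of the ~11.25 ignitions/year,
#' daily mean temperature 16.9 degC, relative humidity ~73%, ~80% of
#' precipitation during March--September, and fire sizes with mean ~5.4 ha
#' and heavy right tail (0.3--80.3 ha).
#'
#' @param seed Integer RNG seed.
#' @param years Archive length in years (>= 1).
#' @param n_rows,n_cols Grid shape (>= 16 each).
#' @param cell_size Cell size in metres.
#' @param relief Elevation relief in metres between valley floor and ridges.
#' @param mean_patch_cells Mean fuel-patch (subcompartment analogue) size in
#'   cells.
#' @param pine_elev_effect Dimensionless strength of the decline of the pine
#'   share with elevation above `pine_elev_threshold`; 0 disables it.
#' @param human_gradient Dimensionless strength of the low-elevation
#'   preference when placing settlements; 0 places them uniformly.
#' @param n_settlements Number of settlements.
#' @param monthly_rates Poisson means of monthly ignition counts
#'   (January..December).
#' @param true_ignition Named numeric vector of generative ignition log-odds
#'   coefficients (must name a subset of the occurrence covariates; an
#'   `(Intercept)` entry is allowed).
#' @param true_size List with fields `intercept`, `b_pine`, `b_log_pop`,
#'   `b_slope`, `sdlog` defining the generative log-size model.
#' @param start_year First calendar year of the archive (365-day years;
#'   February 29 never occurs in the synthetic calendar).
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         years = 20L,
                         n_rows = 100L,
                         n_cols = 100L,
                         cell_size = 200,
                         relief = 1200,
                         mean_patch_cells = 25,
                         pine_elev_effect = 1,
                         human_gradient = 1,
                         n_settlements = 8L,
                         monthly_rates = c(1.6, 1.7, 1.8, 1.5, 0.9, 0.25,
                                           0.2, 0.2, 0.25, 0.35, 0.5, 2.0),
                         true_ignition = c(`(Intercept)` = 0,
                                           prop_pine = 2.5,
                                           prop_fir = 1.5,
                                           prop_broadleaf = -1.0,
                                           dominant_age = -0.02,
                                           slope = -0.02,
                                           aspect = -0.001,
                                           t_avg = -0.06,
                                           rh = -0.08,
                                           dist_road = -0.30,
                                           dist_settlement = -0.45),
                         true_size = list(intercept = -2.9,
                                          b_pine = 3.0,
                                          b_log_pop = 0.4,
                                          b_slope = 0.02,
                                          sdlog = 0.7),
                         start_year = 1991L) {
  if (years < 1) stop("years must be >= 1")
  if (n_rows < 16 || n_cols < 16) stop("grid shape must be at least 16x16")
  if (length(monthly_rates) != 12L || any(monthly_rates < 0))
    stop("monthly_rates must be 12 non-negative values")
  cfg <- list(
    seed = as.integer(seed), years = as.integer(years),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = cell_size,
    # terrain
    base_elev = 168, relief = relief, roughness = 0.18,
    # fuel mosaic
    mean_patch_cells = mean_patch_cells,
    fuel_alpha = c(pine = 0.17, fir = 0.40, broadleaf = 0.18, others = 0.30),
    fuel_conc = 1.2,
    pine_elev_threshold = 700, pine_elev_scale = 250,
    pine_elev_effect = pine_elev_effect,
    age_mean = 17.92, age_sd = 13.72,
    # human activity
    human_gradient = human_gradient,
    n_settlements = as.integer(n_settlements),
    settlement_elev_scale = 150,
    pop_peak_meanlog = log(7000), pop_peak_sdlog = 0.8,
    pop_decay_km = 0.5, town_scale_km = 4,
    # weather
    t_mean = 16.92, t_amp = 9.2, t_ar = 0.75, t_noise_sd = 2.8,
    tmax_offset = 7.95, tmax_sd = 1.5,
    rh_mean = 73.16, rh_noise_sd = 8, rh_temp_coef = 1.2, rh_rain_boost = 6,
    wet_doy = c(60L, 273L), p_wet = 0.55, p_dry = 0.22,
    rain_shape = 0.7, rain_mean_wet = 13, rain_mean_dry = 5.5,
    wind_meanlog = log(1.0), wind_sdlog = 0.55,
    start_year = as.integer(start_year),
    # fire regime
    monthly_rates = monthly_rates,
    true_ignition = true_ignition,
    true_size = true_size,
    spread = spread_params(),
    min_fire_size = 0.3, max_fire_size = 80.3,
    p_lightning = 1 / 225, p_unknown = 0.28,
    weather_half_width = 10L)
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic fire-world configuration\n")
  cat(sprintf("  grid: %d x %d cells @ %g m; archive: %d years from %d\n",
              x$n_rows, x$n_cols, x$cell_size, x$years, x$start_year))
  cat(sprintf("  ignitions/year (sum of monthly rates): %.2f\n",
              sum(x$monthly_rates)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
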