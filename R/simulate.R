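# Stochastic burn-probability engine: ignition timing/location sampling,
# weather draws, arrival-time cellular-automaton spread, size-based
# termination, and per-cell burn-probability accumulation over replicate
# simulated years.

#' Sample monthly ignition counts
#'
#' Independent Poisson draws with the historical monthly mean frequencies.
#'
#' @param rates 12 non-negative monthly means (January..December).
#' @return Integer vector of 12 counts.
#' @export
sample_monthly_counts <- function(rates) {
  if (length(rates) != 12L) stop("need 12 monthly rates")
  if (any(rates < 0)) stop("rates must be non-negative")
  stats::rpois(12L, rates)
}

#' Sample an ignition day within a month
#'
#' Uniform over the days of the (non-leap) month.
#'
#' @param month Month number 1--12.
#' @return Day of month.
#' @export
sample_ignition_date <- function(month) {
  if (month < 1 || month > 12) stop("invalid month")
  sample.int(.month_days[month], 1L)
}

#' Sample an ignition cell from a probability surface
#'
#' Acceptance--rejection with a uniform proposal and envelope equal to the
#' surface maximum: a proposed cell is accepted with probability
#' `surface / max(surface)`, so accepted cells are distributed
#' proportionally to the surface values.
#'
#' @param surface Non-negative matrix (e.g. from [ignition_surface()]).
#' @param n Number of cells to draw.
#' @return `n x 2` matrix of `row`, `col`.
#' @export
sample_ignition_cell <- function(surface, n = 1L) {
  smax <- max(surface)
  if (!is.finite(smax) || smax <= 0) stop("surface has no positive cell")
  nr <- nrow(surface); ncell <- length(surface)
  out <- integer(n); got <- 0L
  batch <- max(64L, 2L * n)
  while (got < n) {
    cand <- sample.int(ncell, batch, replace = TRUE)
    acc <- cand[stats::runif(batch) * smax < surface[cand]]
    take <- min(length(acc), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take)] <- acc[seq_len(take)]
      got <- got + take
    }
  }
  cbind(row = (out - 1L) %% nr + 1L, col = (out - 1L) %/% nr + 1L)
}

#' Spread one fire by arrival-time cellular automaton
#'
#' Fire-arrival-time propagation on the 8-neighbourhood: the time to cross
#' from cell i to neighbour j is the inter-centre distance (diagonals
#' sqrt(2) x cell size) divided by the mean of the two cells' spread rates;
#' cells ignite in arrival-time order (a discrete-event Dijkstra queue) and
#' the fire stops once the burned area reaches `target_ha` or no neighbour
#' is spreadable (rate 0 is an impassable barrier). With
#' `isotropic_slope = FALSE` the terrain multiplier `Kt` is applied per
#' directed edge using the upslope angle from the elevation difference
#' between the two cells (flat or downslope edges get `Kt = 1`); with
#' `isotropic_slope = TRUE` each cell's scalar slope enters its own rate
#' and no directional term is used.
#'
#' @param ignition Length-2 vector `(row, col)`.
#' @param landscape A `fire_landscape`.
#' @param weather_day One-row weather data frame (fixed for the event).
#' @param target_ha Target burned area (ha), >= 0.
#' @param params A [spread_params()].
#' @param isotropic_slope Use the cell's scalar slope instead of the
#'   directional upslope angle.
#' @return List: integer `cells` (linear indices, in ignition order),
#'   `arrival` (minutes), `realized_ha`, and `blocked` (`TRUE` if spread
#'   stopped for want of spreadable neighbours before reaching the target).
#' @export
simulate_fire <- function(ignition, landscape, weather_day, target_ha,
                          params = spread_params(),
                          isotropic_slope = FALSE) {
  nr <- as.integer(landscape$n_rows); nc <- as.integer(landscape$n_cols)
  h <- landscape$cell_size
  cell_area <- (h / 100)^2  # ha
  ignition <- as.integer(ignition)
  start <- (ignition[2L] - 1L) * nr + ignition[1L]
  base <- .base_rate(landscape, weather_day, params, isotropic_slope)
  base[!landscape$mask] <- 0
  n_target <- max(1L, ceiling(target_ha / cell_area))
  if (base[start] <= 0) {
    return(list(cells = start, arrival = 0, realized_ha = cell_area,
                blocked = TRUE))
  }
  elev <- landscape$elevation
  done <- logical(nr * nc)
  cand_id <- start; cand_t <- 0
  settled <- integer(0); settled_t <- numeric(0)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  off_d <- h * c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2))
  while (length(cand_id)) {
    k <- which.min(cand_t)
    cid <- cand_id[k]; ct <- cand_t[k]
    cand_id <- cand_id[-k]; cand_t <- cand_t[-k]
    if (done[cid]) next
    done[cid] <- TRUE
    settled <- c(settled, cid); settled_t <- c(settled_t, ct)
    if (length(settled) >= n_target) break
    r0 <- (cid - 1L) %% nr + 1L
    c0 <- (cid - 1L) %/% nr + 1L
    bi <- base[cid]
    for (j in seq_len(8L)) {
      rj <- r0 + off_r[j]; cj <- c0 + off_c[j]
      if (rj < 1L || rj > nr || cj < 1L || cj > nc) next
      njd <- (cj - 1L) * nr + rj
      if (done[njd]) next
      bj <- base[njd]
      if (bj <= 0) next
      rate <- (bi + bj) / 2
      if (!isotropic_slope) {
        dz <- elev[njd] - elev[cid]
        if (dz > 0) {
          phi <- atan2(dz, off_d[j])
          rate <- rate * exp(params$slope_coef *
                               tan(phi)^params$slope_exp)
        }
      }
      tj <- ct + off_d[j] / rate
      cand_id <- c(cand_id, njd); cand_t <- c(cand_t, tj)
    }
  }
  list(cells = settled, arrival = settled_t,
       realized_ha = length(settled) * cell_area,
       blocked = length(settled) < n_target)
}

# Per-cell base spread rate for a day: R0 * Kw * Kf, with the scalar-slope
# Kt folded in when isotropic_slope = TRUE. R0, Kw are grid constants.
.base_rate <- function(landscape, weather_day, params, isotropic_slope) {
  sr <- spread_rate(weather_day$t_max, weather_day$wind_max, weather_day$rh,
                    phi = 0, fuel_class = "pine", params = params)
  kf <- matrix(params$kf[landscape$fuel_class],
               landscape$n_rows, landscape$n_cols)
  base <- sr$R0 * sr$Kw * kf
  if (isotropic_slope) {
    phi <- pmin(landscape$slope, 89.9)
    base <- base * exp(params$slope_coef * tan(phi * pi / 180)^params$slope_exp)
  }
  base
}

#' Two-sample Kolmogorov--Smirnov test on fire sizes
#'
#' `D` is the supremum gap between the two empirical CDFs; the p-value is
#' taken from the asymptotic Kolmogorov distribution at the effective
#' sample size (ties, which arise from quantised sizes, are tolerated).
#'
#' @param sizes_a,sizes_b Numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(sizes_a, sizes_b) {
  if (!length(sizes_a) || !length(sizes_b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(sizes_a, sizes_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Configuration of a burn-probability simulation
#'
#' @param n_runs Number of replicate simulated years.
#' @param monthly_rates 12 Poisson means of monthly ignition counts.
#' @param half_width Weather-window half-width in days.
#' @param min_size Floor (ha) on drawn target sizes.
#' @param max_size Optional cap (ha) on drawn target sizes (`Inf` for
#'   none).
#' @param isotropic_slope Passed to [simulate_fire()].
#' @param params A [spread_params()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_runs = 10000L, monthly_rates,
                       half_width = 10L, min_size = 0.3, max_size = Inf,
                       isotropic_slope = FALSE, params = spread_params()) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (half_width < 0) stop("half_width must be >= 0")
  if (length(monthly_rates) != 12L || any(monthly_rates < 0))
    stop("monthly_rates must be 12 non-negative values")
  structure(list(n_runs = as.integer(n_runs), monthly_rates = monthly_rates,
                 half_width = as.integer(half_width), min_size = min_size,
                 max_size = max_size, isotropic_slope = isotropic_slope,
                 params = params), class = "sim_config")
}

# Generic interface for the termination-size model: the fitted RF ensemble
# in the analysis pipeline, or the parametric truth in the generator.
draw_size <- function(model, newdata, min_size, max_size) UseMethod("draw_size")

#' @export
draw_size.size_ensemble <- function(model, newdata, min_size, max_size) {
  pmin(draw_stochastic_size(model, newdata, floor = min_size), max_size)
}

#' Generative (ground-truth) fire-size model
#'
#' Lognormal regression used by the synthetic-world generator: the log of
#' the fire size is linear in the pine proportion, log(1 + population
#' density) and slope, plus Gaussian noise, truncated to
#' \[`min`, `max`\] ha.
#'
#' @param intercept,b_pine,b_log_pop,b_slope,sdlog Model parameters.
#' @return Object of class `parametric_size_model`.
#' @export
parametric_size_model <- function(intercept = -1.0, b_pine = 2.3,
                                  b_log_pop = 0.35, b_slope = 0.02,
                                  sdlog = 0.7) {
  structure(list(intercept = intercept, b_pine = b_pine,
                 b_log_pop = b_log_pop, b_slope = b_slope, sdlog = sdlog),
            class = "parametric_size_model")
}

#' @export
draw_size.parametric_size_model <- function(model, newdata, min_size,
                                            max_size) {
  mu <- model$intercept + model$b_pine * newdata$prop_pine +
    model$b_log_pop * log1p(newdata$pop_density) +
    model$b_slope * newdata$slope
  sz <- exp(mu + stats::rnorm(nrow(newdata), 0, model$sdlog))
  pmin(pmax(sz, min_size), max_size)
}

#' Run the stochastic burn-probability simulation
#'
#' For each replicate year: monthly ignition counts are drawn Poisson,
#' each ignition gets a uniform date within its month, a weather day from
#' the +/-`half_width`-day archive window, an ignition cell by
#' acceptance--rejection on that day's ignition-probability surface, and a
#' stochastic target size; the fire is then spread with [simulate_fire()]
#' and its burned cells accumulate into per-cell burn counts. Burn
#' probability is `counts / n_runs`.
#'
#' @param landscape A `fire_landscape`.
#' @param weather Weather archive.
#' @param ignition_fit An `ignition_fit` (fitted or constructed).
#' @param size_model A `size_ensemble` or `parametric_size_model`.
#' @param config A [sim_config()].
#' @param weather_mode `"window"` draws each fire day's weather from the
#'   archive window (burn-probability simulation); `"by_year"` maps run r
#'   to archive year r and uses the actual weather of the sampled date
#'   (used when generating a synthetic fire history).
#' @return Object of class `bp_sim`: `bp` and `counts` matrices, `n_runs`,
#'   and the simulated-fire `catalogue` (run, month, day, doy, cell,
#'   weather row, drawn `size_ha`, CA `realized_ha`, `n_cells`).
#' @export
run_simulation <- function(landscape, weather, ignition_fit, size_model,
                           config, weather_mode = c("window", "by_year")) {
  weather_mode <- match.arg(weather_mode)
  validate_weather(weather)
  nr <- landscape$n_rows; nc <- landscape$n_cols
  n_runs <- config$n_runs
  # --- phase 1: when does each fire happen ------------------------------
  counts <- matrix(stats::rpois(12L * n_runs, config$monthly_rates), 12L,
                   n_runs)
  n_fire <- sum(counts)
  if (n_fire == 0L) {
    bp <- matrix(0, nr, nc)
    return(structure(list(bp = bp, counts = bp, n_runs = n_runs,
                          catalogue = NULL, config = config),
                     class = "bp_sim"))
  }
  run <- rep(rep(seq_len(n_runs), each = 12L), times = as.vector(counts))
  month <- rep(rep.int(seq_len(12L), n_runs), times = as.vector(counts))
  day <- vapply(month, sample_ignition_date, 0L)
  doy <- .month_start[month] + day
  # --- phase 2: weather for each fire -----------------------------------
  if (weather_mode == "window") {
    win <- lapply(1:365, weather_window, weather = weather,
                  half_width = config$half_width)
    widx <- vapply(doy, function(d) {
      ix <- win[[d]]
      ix[sample.int(length(ix), 1L)]
    }, 0L)
  } else {
    yrs <- sort(unique(weather$year))
    if (n_runs > length(yrs))
      stop("by_year weather mode needs one archive year per run")
    widx <- match(sprintf("%04d-%02d-%02d", yrs[run], month, day),
                  weather$date)
  }
  # --- phase 3: ignition cells ------------------------------------------
  cache <- .surface_static(ignition_fit, landscape)
  rows <- integer(n_fire); cols <- integer(n_fire)
  for (i in seq_len(n_fire)) {
    surf <- .surface_from_static(cache, weather[widx[i], ], landscape$mask)
    cell <- sample_ignition_cell(surf, 1L)
    rows[i] <- cell[1L, 1L]; cols[i] <- cell[1L, 2L]
  }
  # --- phase 4: target sizes (batched over all fires) -------------------
  covs <- .cell_covars(landscape, rows, cols)
  covs$wind_velocity <- weather$wind_max[widx]
  covs$rh <- weather$rh[widx]
  covs$t_max <- weather$t_max[widx]
  target <- draw_size(size_model, covs, config$min_size, config$max_size)
  # --- phase 5: spread and accumulate -----------------------------------
  burn_counts <- matrix(0, nr, nc)
  realized <- numeric(n_fire); ncells <- integer(n_fire)
  for (i in seq_len(n_fire)) {
    f <- simulate_fire(c(rows[i], cols[i]), landscape, weather[widx[i], ],
                       target[i], params = config$params,
                       isotropic_slope = config$isotropic_slope)
    burn_counts[f$cells] <- burn_counts[f$cells] + 1
    realized[i] <- f$realized_ha
    ncells[i] <- length(f$cells)
  }
  catalogue <- data.frame(run = run, month = month, day = day, doy = doy,
                          weather_row = widx, row = rows, col = cols,
                          size_ha = target, realized_ha = realized,
                          n_cells = ncells)
  structure(list(bp = burn_counts / n_runs, counts = burn_counts,
                 n_runs = n_runs, catalogue = catalogue, config = config),
            class = "bp_sim")
}

#' @export
print.bp_sim <- function(x, ...) {
  nf <- if (is.null(x$catalogue)) 0L else nrow(x$catalogue)
  cat(sprintf("Burn-probability simulation: %d fires over %d replicate years\n",
              nf, x$n_runs))
  cat(sprintf("  BP: mean %.5f, median %.5f, max %.5f; burned cells: %d\n",
              mean(x$bp), stats::median(x$bp), max(x$bp), sum(x$counts > 0)))
  invisible(x)
}

#' @export
plot.bp_sim <- function(x, ...) {
  # image() draws column 1 at the bottom; flip rows so north stays up
  graphics::image(t(x$bp[nrow(x$bp):1, ]), axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = "Burn probability", ...)
  invisible(x)
}

#' Generate a synthetic fire history
#'
#' Runs the burn-probability machinery once per archive year
#' (`weather_mode = "by_year"`) with the configuration's *true* generative
#' ignition coefficients and parametric size model, then stamps calendar
#' dates and causes (lightning with probability ~1/225, otherwise mostly
#' human) onto the simulated events. The result is a fire catalogue with
#' known ground truth for parameter-recovery tests.
#'
#' @param landscape A `fire_landscape` generated from `config`.
#' @param weather Weather archive generated from `config`.
#' @param config A [synth_config()].
#' @return A `fire_catalogue` data frame: `date`, `row`, `col`, `x`, `y`,
#'   `cause`, `size_ha` (plus the CA footprint columns `realized_ha`,
#'   `n_cells`).
#' @export
gen_fire_history <- function(landscape, weather, config) {
  true_fit <- ignition_model(config$true_ignition)
  true_size <- do.call(parametric_size_model, config$true_size)
  sim <- run_simulation(
    landscape, weather, true_fit, true_size,
    sim_config(n_runs = config$years, monthly_rates = config$monthly_rates,
               half_width = config$weather_half_width,
               min_size = config$min_fire_size,
               max_size = config$max_fire_size,
               params = config$spread),
    weather_mode = "by_year")
  cat_ <- sim$catalogue
  if (is.null(cat_)) {
    return(structure(data.frame(date = character(0), row = integer(0),
                                col = integer(0), x = numeric(0),
                                y = numeric(0), cause = character(0),
                                size_ha = numeric(0),
                                realized_ha = numeric(0),
                                n_cells = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("fire_catalogue", "data.frame")))
  }
  yrs <- sort(unique(weather$year))
  u <- stats::runif(nrow(cat_))
  cause <- ifelse(u < config$p_lightning, "lightning",
                  ifelse(u < config$p_lightning + config$p_unknown,
                         "unknown", "human"))
  out <- data.frame(
    date = sprintf("%04d-%02d-%02d", yrs[cat_$run], cat_$month, cat_$day),
    row = cat_$row, col = cat_$col,
    x = (cat_$col - 0.5) * landscape$cell_size,
    y = (landscape$n_rows - cat_$row + 0.5) * landscape$cell_size,
    cause = cause, size_ha = cat_$size_ha,
    realized_ha = cat_$realized_ha, n_cells = cat_$n_cells,
    stringsAsFactors = FALSE)
  class(out) <- c("fire_catalogue", "data.frame")
  out
}
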