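#' Slope and aspect from an elevation grid
#'
#' Central-difference gradient (one-sided at the borders). Aspect is the
#' downslope azimuth in degrees clockwise from north on (0, 360], with 0
#' reserved for flat cells (zero gradient), which are additionally flagged.
#'
#' @param elevation Elevation matrix in metres, row 1 = north.
#' @param cell_size Cell size in metres.
#' @return List with matrices `slope` (degrees), `aspect` (degrees) and
#'   logical `flat`.
#' @export
terrain_gradient <- function(elevation, cell_size) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  if (nr < 2 || nc < 2) stop("elevation grid too small for a gradient")
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  # east-west derivative
  gx[, 2:(nc - 1)] <- (elevation[, 3:nc] - elevation[, 1:(nc - 2)]) / (2 * cell_size)
  gx[, 1] <- (elevation[, 2] - elevation[, 1]) / cell_size
  gx[, nc] <- (elevation[, nc] - elevation[, nc - 1]) / cell_size
  # north derivative (row index grows southward)
  gy[2:(nr - 1), ] <- (elevation[1:(nr - 2), ] - elevation[3:nr, ]) / (2 * cell_size)
  gy[1, ] <- (elevation[1, ] - elevation[2, ]) / cell_size
  gy[nr, ] <- (elevation[nr - 1, ] - elevation[nr, ]) / cell_size
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  flat <- gx == 0 & gy == 0
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[!flat & aspect == 0] <- 360
  aspect[flat] <- 0
  list(slope = slope, aspect = aspect, flat = flat)
}

#' Generate synthetic terrain
#'
#' Multi-scale surface: a smooth elevation field rising away from one
#' meandering valley (the dominant landform), plus low-amplitude spectral
#' roughness from a handful of random cosine waves. Slope and aspect follow
#' from [terrain_gradient()]. Consumes the current RNG stream.
#'
#' @param config A [synth_config()].
#' @return List with `elevation`, `slope`, `aspect`, `flat` matrices and the
#'   valley row path `valley_row` (one row index per column).
#' @export
gen_terrain <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  if (nr < 16 || nc < 16) stop("degenerate grid shape; need at least 16x16")
  h <- config$cell_size
  u <- seq_len(nc) / nc
  ph <- stats::runif(2, 0, 2 * pi)
  vrow <- nr * (0.5 + 0.22 * sin(2 * pi * 1.3 * u + ph[1]) +
                  0.08 * sin(2 * pi * 3.1 * u + ph[2]))
  vrow <- pmin(pmax(vrow, 3), nr - 2)
  rows <- matrix(seq_len(nr), nr, nc)
  dval <- abs(rows - matrix(vrow, nr, nc, byrow = TRUE)) * h
  base <- config$relief * (dval / max(dval))^0.9
  # spectral roughness
  xg <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr) / nr, nr, nc)
  rough <- matrix(0, nr, nc)
  for (k in seq_len(8)) {
    f <- stats::runif(1, 0.5, 4)
    th <- stats::runif(1, 0, 2 * pi)
    phk <- stats::runif(1, 0, 2 * pi)
    rough <- rough + (1 / f) * cos(2 * pi * f * (cos(th) * xg + sin(th) * yg) + phk)
  }
  rough <- rough / stats::sd(rough)
  elevation <- config$base_elev + base + config$roughness * config$relief * 0.5 *
    (rough - min(rough)) / diff(range(rough))
  g <- terrain_gradient(elevation, h)
  list(elevation = elevation, slope = g$slope, aspect = g$aspect,
       flat = g$flat, valley_row = vrow)
}

# Minimum squared distance (in cells) from every grid cell to a set of
# source cells; optionally accumulates a kernel sum instead.
.min_dist2 <- function(nr, nc, src_rows, src_cols) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_along(src_rows)) {
    d2 <- pmin(d2, (rows - src_rows[i])^2 + (cols - src_cols[i])^2)
  }
  d2
}

#' Generate the fuel mosaic and stand ages
#'
#' Voronoi patches (nearest random seed cell) stand in for forest-survey
#' subcompartments. Each patch draws its four fuel-type proportions from a
#' Dirichlet distribution whose pine concentration decays with patch mean
#' elevation above a threshold, and a stand age from a gamma distribution.
#' The dominant `fuel_class` per cell is the largest-proportion type.
#'
#' @param config A [synth_config()].
#' @param elevation Elevation matrix from [gen_terrain()].
#' @return List with matrices `prop_pine`, `prop_fir`, `prop_broadleaf`,
#'   `prop_others`, `dominant_age`, integer `patch_id` and character
#'   `fuel_class`.
#' @export
gen_fuel_mosaic <- function(config, elevation) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  ncell <- nr * nc
  npatch <- max(4L, round(ncell / config$mean_patch_cells))
  seeds <- sample.int(ncell, npatch)
  sr <- (seeds - 1L) %% nr + 1L
  sc <- (seeds - 1L) %/% nr + 1L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # nearest-seed labelling in blocks to bound memory
  pid <- matrix(NA_integer_, nr, nc)
  best <- matrix(Inf, nr, nc)
  for (i in seq_len(npatch)) {
    d2 <- (rows - sr[i])^2 + (cols - sc[i])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    pid[upd] <- i
  }
  elev_p <- vapply(seq_len(npatch), function(i) mean(elevation[pid == i]), 0)
  alpha0 <- config$fuel_alpha * config$fuel_conc
  props <- matrix(0, npatch, 4L,
                  dimnames = list(NULL, c("pine", "fir", "broadleaf", "others")))
  for (i in seq_len(npatch)) {
    a <- alpha0
    a["pine"] <- a["pine"] * exp(-config$pine_elev_effect *
                                   pmax(0, elev_p[i] - config$pine_elev_threshold) /
                                   config$pine_elev_scale)
    g <- stats::rgamma(4L, shape = a)
    while (sum(g) <= 0) g <- stats::rgamma(4L, shape = a)
    props[i, ] <- g / sum(g)
  }
  shp <- (config$age_mean / config$age_sd)^2
  age_p <- stats::rgamma(npatch, shape = shp, rate = shp / config$age_mean)
  cls <- colnames(props)[max.col(props, ties.method = "first")]
  lay <- function(v) matrix(v[pid], nr, nc)
  list(prop_pine = lay(props[, "pine"]),
       prop_fir = lay(props[, "fir"]),
       prop_broadleaf = lay(props[, "broadleaf"]),
       prop_others = lay(props[, "others"]),
       dominant_age = lay(age_p),
       patch_id = matrix(pid, nr, nc),
       fuel_class = matrix(cls[pid], nr, nc))
}

#' Generate human-activity layers
#'
#' A road polyline traces the valley floor, with branch roads connecting
#' each settlement to it. Settlements are placed preferentially at low
#' elevation (strength set by the `human_gradient` knob) and cluster
#' around a town centre, so the access gradient also runs *along* the
#' valley rather than only across it. Distance layers are exact Euclidean
#' distances (km) from each cell centre to the nearest road cell /
#' settlement cell; population density is a sum of per-settlement
#' exponential kernels.
#'
#' @param config A [synth_config()].
#' @param terrain Output of [gen_terrain()].
#' @return List with matrices `pop_density`, `dist_road`, `dist_settlement`,
#'   plus `road_cells` and `settlement_cells` (two-column row/col matrices).
#' @export
gen_human_layers <- function(config, terrain) {
  elevation <- terrain$elevation
  nr <- nrow(elevation); nc <- ncol(elevation)
  km <- config$cell_size / 1000
  road_r <- as.integer(round(terrain$valley_row))
  road_c <- seq_len(nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  w <- exp(-config$human_gradient * (elevation - min(elevation)) /
             config$settlement_elev_scale)
  centre <- sample.int(nr * nc, 1L, prob = as.vector(w))
  cen_r <- (centre - 1L) %% nr + 1L
  cen_c <- (centre - 1L) %/% nr + 1L
  d_cen <- sqrt((rows - cen_r)^2 + (cols - cen_c)^2) * km
  w <- w * exp(-d_cen / config$town_scale_km)
  stl <- c(centre,
           sample.int(nr * nc, config$n_settlements - 1L,
                      prob = as.vector(w)))
  stl_r <- (stl - 1L) %% nr + 1L
  stl_c <- (stl - 1L) %/% nr + 1L
  # branch roads: straight line from each settlement to the valley road
  for (i in seq_along(stl_r)) {
    j <- which.min((road_r - stl_r[i])^2 + (road_c - stl_c[i])^2)
    nstep <- max(abs(road_r[j] - stl_r[i]), abs(road_c[j] - stl_c[i]))
    if (nstep > 0L) {
      tt <- seq(0, 1, length.out = nstep + 1L)
      road_r <- c(road_r, as.integer(round(stl_r[i] + tt * (road_r[j] - stl_r[i]))))
      road_c <- c(road_c, as.integer(round(stl_c[i] + tt * (road_c[j] - stl_c[i]))))
    }
  }
  d2road <- .min_dist2(nr, nc, road_r, road_c)
  d2stl <- matrix(Inf, nr, nc)
  pop <- matrix(0, nr, nc)
  peaks <- stats::rlnorm(config$n_settlements, config$pop_peak_meanlog,
                         config$pop_peak_sdlog)
  for (i in seq_len(config$n_settlements)) {
    d2 <- (rows - stl_r[i])^2 + (cols - stl_c[i])^2
    d2stl <- pmin(d2stl, d2)
    pop <- pop + peaks[i] * exp(-sqrt(d2) * km / config$pop_decay_km)
  }
  list(pop_density = pop,
       dist_road = sqrt(d2road) * km,
       dist_settlement = sqrt(d2stl) * km,
       road_cells = cbind(row = road_r, col = road_c),
       settlement_cells = cbind(row = stl_r, col = stl_c))
}

#' Generate a complete synthetic landscape
#'
#' Seeds the RNG from `config$seed` and runs [gen_terrain()],
#' [gen_fuel_mosaic()] and [gen_human_layers()] in a fixed order, so an
#' identical configuration reproduces a bit-identical landscape.
#'
#' @param config A [synth_config()].
#' @return A `fire_landscape` object: grid metadata plus the co-registered
#'   covariate layers (all matrices, row 1 = north).
#' @export
synth_landscape <- function(config) {
  set.seed(config$seed)
  terr <- gen_terrain(config)
  fuel <- gen_fuel_mosaic(config, terr$elevation)
  hum <- gen_human_layers(config, terr)
  structure(list(
    n_rows = config$n_rows, n_cols = config$n_cols,
    cell_size = config$cell_size,
    elevation = terr$elevation, slope = terr$slope, aspect = terr$aspect,
    flat = terr$flat,
    prop_pine = fuel$prop_pine, prop_fir = fuel$prop_fir,
    prop_broadleaf = fuel$prop_broadleaf, prop_others = fuel$prop_others,
    dominant_age = fuel$dominant_age, patch_id = fuel$patch_id,
    fuel_class = fuel$fuel_class,
    pop_density = hum$pop_density, dist_road = hum$dist_road,
    dist_settlement = hum$dist_settlement,
    road_cells = hum$road_cells, settlement_cells = hum$settlement_cells,
    mask = matrix(TRUE, config$n_rows, config$n_cols)),
    class = "fire_landscape")
}

#' @export
print.fire_landscape <- function(x, ...) {
  cat(sprintf("fire_landscape: %d x %d cells @ %g m (%.1f km^2)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_rows * x$n_cols * (x$cell_size / 1000)^2))
  cat(sprintf("  elevation %.0f-%.0f m; fuel classes: %s\n",
              min(x$elevation), max(x$elevation),
              paste(names(sort(table(x$fuel_class), decreasing = TRUE)),
                    collapse = " > ")))
  cat(sprintf("  %d settlements, %d road cells\n",
              nrow(x$settlement_cells), nrow(x$road_cells)))
  invisible(x)
}

#' Per-cell covariate table of a landscape
#'
#' @param x A `fire_landscape`.
#' @param row.names,optional,... Unused, for generic consistency.
#' @return Data frame with one row per cell: `row`, `col`, projected `x`,
#'   `y` (lower-left origin), all numeric layers and `fuel_class`.
#' @export
as.data.frame.fire_landscape <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  nr <- x$n_rows; nc <- x$n_cols
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(
    row = rows, col = cols,
    x = (cols - 0.5) * x$cell_size,
    y = (nr - rows + 0.5) * x$cell_size,
    elevation = as.vector(x$elevation),
    slope = as.vector(x$slope),
    aspect = as.vector(x$aspect),
    prop_pine = as.vector(x$prop_pine),
    prop_fir = as.vector(x$prop_fir),
    prop_broadleaf = as.vector(x$prop_broadleaf),
    prop_others = as.vector(x$prop_others),
    dominant_age = as.vector(x$dominant_age),
    pop_density = as.vector(x$pop_density),
    dist_road = as.vector(x$dist_road),
    dist_settlement = as.vector(x$dist_settlement),
    fuel_class = as.vector(x$fuel_class),
    stringsAsFactors = FALSE)
}

#' Write all numeric landscape layers as Esri ASCII grids
#'
#' @param landscape A `fire_landscape`.
#' @param dir Output directory (created if missing).
#' @return Vector of written paths, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layers <- c("elevation", "slope", "aspect", "prop_pine", "prop_fir",
              "prop_broadleaf", "prop_others", "dominant_age",
              "pop_density", "dist_road", "dist_settlement")
  paths <- vapply(layers, function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(landscape[[nm]], p, cell_size = landscape$cell_size)
    p
  }, "")
  invisible(paths)
}
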