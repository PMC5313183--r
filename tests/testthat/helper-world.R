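# Fixtures built in code: homogeneous hand-made landscapes for the spread
# engine, one-row weather days, and a cached small synthetic world shared
# by the slower model-fitting tests.

make_landscape <- function(nr = 20, nc = 20, cell_size = 200,
                           elevation = 0, fuel = "pine",
                           mask = NULL) {
  m <- function(v) matrix(v, nr, nc)
  elev <- if (is.matrix(elevation)) elevation else m(elevation)
  g <- terrain_gradient(elev, cell_size)
  structure(list(
    n_rows = nr, n_cols = nc, cell_size = cell_size,
    elevation = elev, slope = g$slope, aspect = g$aspect, flat = g$flat,
    prop_pine = m(as.numeric(fuel == "pine")),
    prop_fir = m(as.numeric(fuel == "fir")),
    prop_broadleaf = m(as.numeric(fuel == "broadleaf")),
    prop_others = m(as.numeric(fuel == "others")),
    dominant_age = m(18), patch_id = m(1L),
    fuel_class = m(fuel),
    pop_density = m(100), dist_road = m(1), dist_settlement = m(2),
    road_cells = cbind(row = 1L, col = 1L),
    settlement_cells = cbind(row = 1L, col = 1L),
    mask = if (is.null(mask)) m(TRUE) else mask),
    class = "fire_landscape")
}

make_weather_day <- function(t_max = 30, t_avg = 20, rh = 50, precip = 0,
                             wind_dir = 1L, wind_max = 2) {
  data.frame(date = "2000-01-15", year = 2000L, month = 1L, day = 15L,
             doy = 15L, t_max = t_max, t_avg = t_avg, rh = rh,
             precip = precip, wind_dir = wind_dir, wind_max = wind_max)
}

# One small world (60x60, 10 y) fitted once and reused across tests.
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 42L, n_rows = 60L, n_cols = 60L,
                          years = 10L)
      L <- synth_landscape(cfg)
      W <- gen_weather(cfg)
      set.seed(cfg$seed)
      H <- gen_fire_history(L, W, cfg)
      cache <<- list(cfg = cfg, landscape = L, weather = W, history = H)
    }
    cache
  }
})

# All-orderings lmg oracle: average sequential R^2 gains over every
# permutation, fitting each submodel with lm(). Independent of the
# package's subset-caching implementation.
lmg_bruteforce <- function(data) {
  y <- data[[1L]]
  x <- as.data.frame(data[-1L])
  p <- ncol(x)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ ., data = x[, cols, drop = FALSE]))$r.squared
  }
  shares <- stats::setNames(numeric(p), names(x))
  all_p <- perms(seq_len(p))
  for (ord in all_p) {
    prev <- 0
    for (j in seq_along(ord)) {
      cur <- r2_of(ord[seq_len(j)])
      shares[ord[j]] <- shares[ord[j]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(all_p)
}

# Dijkstra burned-set oracle on igraph shortest-path arrival times, with
# the same edge-weight contract as the spread engine but an independent
# propagation algorithm.
dijkstra_burn_oracle <- function(ignition, landscape, weather_day,
                                 target_ha, params = spread_params(),
                                 isotropic_slope = FALSE) {
  nr <- landscape$n_rows; nc <- landscape$n_cols
  h <- landscape$cell_size
  cell_area <- (h / 100)^2
  sr <- spread_rate(weather_day$t_max, weather_day$wind_max,
                    weather_day$rh, 0, "pine", params)
  kf <- matrix(params$kf[landscape$fuel_class], nr, nc)
  base <- sr$R0 * sr$Kw * kf
  if (isotropic_slope)
    base <- base * exp(params$slope_coef *
                         tan(pmin(landscape$slope, 89.9) * pi / 180)^params$slope_exp)
  base[!landscape$mask] <- 0
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]
    dd <- h * sqrt(dr^2 + dc^2)
    rs <- seq_len(nr)[(seq_len(nr) + dr) >= 1 & (seq_len(nr) + dr) <= nr]
    cs <- seq_len(nc)[(seq_len(nc) + dc) >= 1 & (seq_len(nc) + dc) <= nc]
    i_idx <- as.vector(outer(rs, (cs - 1L) * nr, `+`))
    j_idx <- as.vector(outer(rs + dr, (cs + dc - 1L) * nr, `+`))
    ok <- base[i_idx] > 0 & base[j_idx] > 0
    rate <- (base[i_idx[ok]] + base[j_idx[ok]]) / 2
    if (!isotropic_slope) {
      dz <- landscape$elevation[j_idx[ok]] - landscape$elevation[i_idx[ok]]
      up <- dz > 0
      rate[up] <- rate[up] * exp(params$slope_coef *
                                   tan(atan2(dz[up], dd))^params$slope_exp)
    }
    from <- c(from, i_idx[ok]); to <- c(to, j_idx[ok])
    wt <- c(wt, dd / rate)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nr * nc)))
  start <- (ignition[2L] - 1L) * nr + ignition[1L]
  d <- igraph::distances(g, v = as.character(start), mode = "out",
                         weights = igraph::E(g)$weight)[1L, ]
  d <- stats::setNames(as.numeric(d), names(d))
  reach <- sort(d[is.finite(d)])
  n_target <- max(1L, ceiling(target_ha / cell_area))
  as.integer(names(reach))[seq_len(min(n_target, length(reach)))]
}
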