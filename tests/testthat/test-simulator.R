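test_that("spread-rate arithmetic follows the printed model", {
  p <- spread_params()
  # R0 = 0.03*30 + 0.05*2 + 0.01*(1 - 0.5) - 0.3 = 0.705 m/min
  r <- spread_rate(30, 2, 50, 0, "fir", p)
  expect_equal(r$R0, 0.705, tolerance = 1e-12)
  # no wind, flat ground: both multipliers collapse to 1
  r0 <- spread_rate(25, 0, 40, 0, "pine", p)
  expect_equal(r0$Kw, 1)
  expect_equal(r0$Kt, 1)
  expect_equal(r0$R, r0$R0 * p$kf[["pine"]])
  # cold, still, saturated air: R0 < 0 clamps to no spread
  expect_equal(spread_rate(0, 0, 100, 0, "pine", p)$R, 0)
  # monotone in wind and slope when burning
  v <- spread_rate(30, c(0, 1, 2, 4), 50, 0, "pine", p)$R
  expect_true(all(diff(v) > 0))
  s <- spread_rate(30, 2, 50, c(0, 10, 20, 40), "pine", p)$R
  expect_true(all(diff(s) > 0))
  expect_error(spread_rate(30, 2, 50, 90, "pine", p), "slope angle")
  expect_error(spread_rate(30, 2, 150, 0, "pine", p), "rh")
  expect_error(spread_params(kf = c(pine = 2, fir = 1, broadleaf = 0.8,
                                    others = 0.9)), "0.8")
})

test_that("monthly ignition counts are Poisson with the given means", {
  expect_equal(sample_monthly_counts(rep(0, 12)), rep(0L, 12))
  expect_error(sample_monthly_counts(c(rep(1, 11), -1)), "non-negative")
  set.seed(100)
  draws <- replicate(10000, sample_monthly_counts(c(3, rep(0.5, 11))))
  expect_lt(abs(mean(draws[1, ]) - 3), 0.05)
  disp <- apply(draws, 1, var) / apply(draws, 1, mean)  # ~1 for Poisson
  expect_true(all(abs(disp - 1) < 0.1))
})

test_that("ignition dates are uniform over the month's days", {
  set.seed(101)
  feb <- replicate(5000, sample_ignition_date(2))
  expect_setequal(sort(unique(feb)), 1:28)
  expect_gt(stats::chisq.test(table(factor(feb, levels = 1:28)))$p.value,
            0.01)
  set.seed(5); a <- sample_ignition_date(7)
  set.seed(5); b <- sample_ignition_date(7)
  expect_identical(a, b)
})

test_that("acceptance-rejection cell sampling is proportional to the surface", {
  one <- matrix(0, 5, 5); one[3, 4] <- 0.2
  set.seed(102)
  hits <- sample_ignition_cell(one, 200)
  expect_true(all(hits[, "row"] == 3 & hits[, "col"] == 4))
  two <- matrix(c(0.2, 0.6), 1, 2)
  set.seed(103)
  d <- sample_ignition_cell(two, 10000)
  expect_lt(abs(mean(d[, "col"] == 2) - 0.75), 0.02)
  expect_error(sample_ignition_cell(matrix(0, 3, 3)), "positive")
})

test_that("uniform surface draws pass a chi-square uniformity check", {
  set.seed(104)
  u <- sample_ignition_cell(matrix(0.3, 4, 4), 8000)
  idx <- (u[, "col"] - 1) * 4 + u[, "row"]
  expect_gt(stats::chisq.test(table(factor(idx, levels = 1:16)))$p.value,
            0.01)
})

test_that("single-cell targets and zero-rate barriers bound the burn", {
  L <- make_landscape(15, 15)
  wd <- make_weather_day()
  f <- simulate_fire(c(8, 8), L, wd, target_ha = 0.1)
  expect_identical(f$cells, (8L - 1L) * 15L + 8L)
  expect_equal(f$realized_ha, 4)  # one 200 m cell
  # closed unburnable ring: the fire can never cross it
  msk <- matrix(TRUE, 15, 15)
  msk[5, 5:11] <- msk[11, 5:11] <- msk[5:11, 5] <- msk[5:11, 11] <- FALSE
  Lr <- make_landscape(15, 15, mask = msk)
  g <- simulate_fire(c(8, 8), Lr, wd, target_ha = 1e6)
  rows <- (g$cells - 1L) %% 15L + 1L
  cols <- (g$cells - 1L) %/% 15L + 1L
  expect_true(all(rows > 5 & rows < 11 & cols > 5 & cols < 11))
  expect_true(g$blocked)
  # ignition on an unburnable cell: recorded, no spread
  h <- simulate_fire(c(5, 5), Lr, wd, target_ha = 50)
  expect_length(h$cells, 1L)
})

test_that("realized size overshoots the target by less than one cell", {
  set.seed(105)
  for (i in 1:20) {
    nr <- 25
    elev <- matrix(cumsum(rnorm(nr * nr, 0, 5)), nr, nr)
    L <- make_landscape(nr, nr, elevation = elev,
                        fuel = sample(c("pine", "fir", "broadleaf"), 1))
    target <- runif(1, 0.3, 60)
    f <- simulate_fire(c(13, 13), L, make_weather_day(), target)
    if (!f$blocked) {
      expect_gte(f$realized_ha, min(target, 4))
      expect_lt(f$realized_ha - target, 4)  # < one 200 m cell layer
    }
  }
})

test_that("CA burned set matches the Dijkstra arrival-time oracle", {
  skip_if_not_installed("igraph")
  set.seed(106)
  for (i in 1:6) {
    nr <- 20
    elev <- 500 + matrix(cumsum(rnorm(nr * nr, 0, 8)), nr, nr)
    L <- make_landscape(nr, nr, elevation = elev, fuel = "pine")
    # carve random unburnable obstacles
    L$mask[sample(nr * nr, 40)] <- FALSE
    ign <- c(10L, 10L); L$mask[10, 10] <- TRUE
    wd <- make_weather_day(t_max = runif(1, 20, 35), rh = runif(1, 30, 70),
                           wind_max = runif(1, 0, 3))
    target <- runif(1, 5, 150)
    mine <- simulate_fire(ign, L, wd, target)
    oracle <- dijkstra_burn_oracle(ign, L, wd, target)
    expect_setequal(mine$cells, oracle)
  }
})

test_that("weather draw modes and run accounting stay consistent", {
  w <- shared_world()
  cfg <- w$cfg
  truth <- ignition_model(cfg$true_ignition)
  szm <- do.call(parametric_size_model, cfg$true_size)
  sc <- sim_config(n_runs = 50, monthly_rates = cfg$monthly_rates,
                   max_size = cfg$max_fire_size, params = cfg$spread)
  set.seed(200)
  sim <- run_simulation(w$landscape, w$weather, truth, szm, sc)
  # conservation: accumulated burn counts equal summed footprints
  expect_equal(sum(sim$counts), sum(sim$catalogue$n_cells))
  expect_true(all(sim$bp >= 0 & sim$bp <= 1))
  expect_true(all(abs(sim$bp * sim$n_runs - round(sim$bp * sim$n_runs)) <
                    1e-9))
  # expected ignitions per run = sum of monthly rates (3 SE band)
  lambda <- sum(cfg$monthly_rates)
  se <- sqrt(lambda / 50)
  expect_lt(abs(nrow(sim$catalogue) / 50 - lambda), 3 * se)
  # determinism under an identical seed
  set.seed(200)
  sim2 <- run_simulation(w$landscape, w$weather, truth, szm, sc)
  expect_identical(sim$bp, sim2$bp)
  expect_identical(sim$catalogue, sim2$catalogue)
  # zero rates: nothing burns
  sc0 <- sim_config(n_runs = 1, monthly_rates = rep(0, 12))
  s0 <- run_simulation(w$landscape, w$weather, truth, szm, sc0)
  expect_true(all(s0$bp == 0))
})

test_that("two-sample KS statistic matches hand-computed ECDF gaps", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("fire history carries the seasonal and size structure", {
  w <- shared_world()
  H <- w$history
  expect_gt(nrow(H), 0)
  months <- as.integer(substr(H$date, 6, 7))
  expect_gt(mean(months %in% c(12, 1:5)), 0.6)  # winter-spring season
  expect_true(all(H$size_ha >= 0.3))
  expect_true(all(H$realized_ha >= (w$cfg$cell_size / 100)^2 - 1e-9))
  expect_true(all(H$row >= 1 & H$row <= 60 & H$col >= 1 & H$col <= 60))
  expect_true(all(H$cause %in% c("human", "lightning", "unknown")))
  expect_true(all(substr(H$date, 1, 4) %in%
                    as.character(unique(w$weather$year))))
  # identical config implies an identical history
  cfg2 <- synth_config(seed = 42L, n_rows = 60L, n_cols = 60L, years = 10L)
  L2 <- synth_landscape(cfg2); W2 <- gen_weather(cfg2)
  set.seed(cfg2$seed)
  H2 <- gen_fire_history(L2, W2, cfg2)
  expect_identical(H, H2)
  # zero monthly rates produce an empty catalogue
  cfg0 <- synth_config(seed = 1L, n_rows = 20L, n_cols = 20L, years = 2L,
                       monthly_rates = rep(0, 12))
  L0 <- synth_landscape(cfg0); W0 <- gen_weather(cfg0)
  expect_equal(nrow(gen_fire_history(L0, W0, cfg0)), 0L)
})
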