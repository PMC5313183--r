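test_that("orthogonal regressors get exactly their univariate R-squared", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)  # exactly orthogonal to x1
  set.seed(1)
  y <- 0.9 * x1 - 0.4 * x2 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  sh <- lmg(d)
  expect_equal(unname(sh["x1"]), stats::cor(y, x1)^2, tolerance = 1e-10)
  expect_equal(unname(sh["x2"]), stats::cor(y, x2)^2, tolerance = 1e-10)
})

test_that("exact lmg equals the all-orderings brute force for small p", {
  set.seed(2)
  n <- 80
  # correlated design
  z <- rnorm(n)
  d3 <- data.frame(y = NA, a = z + rnorm(n), b = 0.7 * z + rnorm(n),
                   c = rnorm(n))
  d3$y <- d3$a - 0.5 * d3$b + 0.3 * d3$c + rnorm(n)
  sh <- lmg(d3)
  expect_equal(unname(sh), unname(lmg_bruteforce(d3)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # p = 5 with stronger collinearity
  d5 <- data.frame(y = NA, v1 = z, v2 = z + 0.5 * rnorm(n),
                   v3 = rnorm(n), v4 = rnorm(n),
                   v5 = 0.5 * z + rnorm(n))
  d5$y <- d5$v1 + d5$v3 - d5$v5 + rnorm(n)
  sh5 <- lmg(d5)
  expect_equal(unname(sh5), unname(lmg_bruteforce(d5)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(sh5), attr(sh5, "r2"), tolerance = 1e-9)
})

test_that("shares always sum to the full-model R-squared", {
  set.seed(3)
  for (i in 1:5) {
    n <- 60; p <- sample(2:7, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- x %*% rnorm(p) + rnorm(n)
    d <- data.frame(y = y, x)
    sh <- lmg(d)
    full <- summary(stats::lm(y ~ ., data = d))$r.squared
    expect_equal(sum(sh), full, tolerance = 1e-9)
  }
})

test_that("duplicated regressors split their joint share symmetrically", {
  set.seed(4)
  n <- 50
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  d <- data.frame(y = y, a = x, b = x, c = rnorm(n))
  sh <- lmg(d)
  expect_true(attr(sh, "singular"))
  expect_equal(unname(sh["a"]), unname(sh["b"]), tolerance = 1e-9)
})

test_that("lmg is invariant to regressor column order", {
  set.seed(5)
  n <- 70
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- d$a + 0.5 * d$b + rnorm(n)
  s1 <- lmg(d)
  s2 <- lmg(d[c("y", "c", "a", "b")])
  expect_equal(s1[c("a", "b", "c")], s2[c("a", "b", "c")],
               tolerance = 1e-12)
})

test_that("sampled-permutation mode approximates the exact shares", {
  set.seed(6)
  n <- 100
  x <- matrix(rnorm(n * 4), n, 4)
  d <- data.frame(y = x %*% c(1, 0.5, 0, -0.7) + rnorm(n), x)
  exact <- lmg(d)
  approx <- lmg(d, max_exact = 2L, n_perm = 4000L)
  expect_false(attr(approx, "exact"))
  expect_equal(unname(exact), unname(approx), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("OLS wrapper reports closed-form answers and flags rank loss", {
  set.seed(7)
  n <- 40
  x <- rnorm(n)
  y <- 3 + 2 * x  # exact line
  f <- suppressWarnings(ols_fit(data.frame(y = y, x = x)))  # perfect fit
  expect_equal(f$r2, 1)
  expect_equal(f$table$B[2], stats::cov(x, y) / stats::var(x),
               tolerance = 1e-10)
  dup <- data.frame(y = y + rnorm(n), a = x, b = x)
  expect_error(ols_fit(dup), "aliased.*b")
})

test_that("group shares partition the variable shares", {
  sh <- c(prop_pine = 0.05, prop_fir = 0.02, prop_broadleaf = 0.01,
          dominant_age = 0.02, slope = 0.03, elevation = 0.10,
          dist_road = 0.40)
  g <- group_shares(sh)
  expect_equal(sum(g$share), sum(sh), tolerance = 1e-12)
  expect_equal(g$group[1], "human")
  one <- group_shares(c(a = 0.3, b = 0.2), grouping = list(all = c("a", "b")))
  expect_equal(one$share, 0.5)
  expect_error(group_shares(c(zzz = 0.1)), "no group")
})

test_that("BP regression data respects the zero-cell contract", {
  L <- make_landscape(12, 12)
  # spatially varying layers so the design has full rank
  set.seed(8)
  for (v in c("prop_pine", "prop_fir", "prop_broadleaf", "dominant_age",
              "slope", "elevation", "dist_road"))
    L[[v]] <- matrix(runif(144), 12, 12)
  bp <- matrix(0, 12, 12)
  expect_error(build_bp_regression(bp, L, n_runs = 100), "usable cells")
  bp[sample(144, 60)] <- sample(1:5, 60, replace = TRUE) / 100
  d <- build_bp_regression(bp, L, zero_cells = "exclude")
  expect_equal(nrow(d), sum(bp > 0))
  expect_true(all(is.finite(d$log_bp)))
  df <- build_bp_regression(bp, L, zero_cells = "floor", n_runs = 100)
  expect_equal(nrow(df), 144L)
  expect_true(all(is.finite(df$log_bp)))
  expect_equal(min(df$log_bp), log(1 / 200))
})
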