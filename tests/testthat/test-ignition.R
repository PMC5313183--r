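test_that("mean nearest-neighbour distance matches hand enumeration", {
  expect_equal(mean_nn_distance(cbind(c(0, 500), c(0, 0))), 500)
  # collinear points at 0, 100, 300 m: neighbours 100, 100, 200
  expect_equal(mean_nn_distance(cbind(c(0, 100, 300), 0)), 400 / 3,
               tolerance = 1e-12)
  # isometry invariance
  set.seed(1)
  pts <- matrix(runif(20, 0, 1000), ncol = 2)
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
    matrix(c(123, -456), 10, 2, byrow = TRUE)
  expect_equal(mean_nn_distance(rot), mean_nn_distance(pts))
  expect_error(mean_nn_distance(cbind(1, 1)), "2 points")
})

test_that("non-ignition sampling respects the exclusion radius", {
  mask <- matrix(TRUE, 50, 50)
  cs <- 200
  centre <- cbind(25.5 * cs, 25.5 * cs)  # roughly mid-grid
  set.seed(7)
  pts <- sample_nonignitions(centre, mask, cs, 1000, min_dist = 10 * cs)
  d <- sqrt((pts$x - centre[1])^2 + (pts$y - centre[2])^2)
  expect_equal(sum(d < 10 * cs), 0)  # brute-force check on all 1000 draws
  expect_equal(nrow(pts), 1000)
  # min_dist 0 reduces to a plain uniform sample of size n
  set.seed(8)
  p0 <- sample_nonignitions(centre, mask, cs, 57, min_dist = 0)
  expect_equal(nrow(p0), 57)
  # infeasible radius errors after the proposal cap
  expect_error(
    sample_nonignitions(centre, mask, cs, 5, min_dist = 1e6,
                        max_tries = 2000),
    "mask too small")
})

test_that("collinearity screen drops the lower-priority member of each pair", {
  set.seed(42)
  n <- 10000
  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  scr <- screen_collinearity(ind, threshold = 0.4)
  expect_setequal(scr$retained, c("a", "b", "c"))  # |r| << 0.4 at this n
  dup <- data.frame(x = ind$a, y = ind$a, z = ind$b)
  scr2 <- screen_collinearity(dup, threshold = 0.4,
                              priority = c(2, 1, 3))
  expect_setequal(scr2$retained, c("x", "z"))
  expect_equal(scr2$dropped$dropped, "y")
  # threshold 1 retains everything except exact duplicates
  mix <- data.frame(x = ind$a, y = ind$a,
                    w = 0.9 * ind$a + sqrt(1 - 0.81) * ind$b)
  scr3 <- screen_collinearity(mix, threshold = 1.0)
  expect_length(scr3$retained, 2L)
  expect_true("w" %in% scr3$retained)
  expect_warning(screen_collinearity(data.frame(k = rep(1, 10), a = rnorm(10),
                                                b = rnorm(10))),
                 "constant")
})

test_that("logistic fit reproduces its algebraic identities on real fits", {
  w <- shared_world()
  set.seed(5)
  occ <- build_occurrence_sample(w$history, w$landscape, w$weather)
  fit <- fit_ignition(occ)
  tab <- fit$table
  expect_equal(tab$ExpB, exp(tab$B), tolerance = 1e-12)
  expect_equal(tab$Wald, (tab$B / tab$SE)^2, tolerance = 1e-9)
  expect_gte(fit$L1, fit$L0)
  d <- fit$diagnostics
  expect_gte(d$nagelkerke_r2, d$cox_snell_r2)
  expect_true(d$auc > 0.5 && d$auc <= 1)
  # the baseline fuel proportion never enters
  expect_false("prop_others" %in% tab$variable)
})

test_that("true coefficients fall in the 95% Wald interval at nominal rate", {
  set.seed(314)
  beta <- c(0.8, -0.5, 0)
  n <- 450
  hits <- replicate(100, {
    x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    p <- plogis(-0.2 + x %*% beta)
    d <- data.frame(ignited = rbinom(n, 1, p), x)
    f <- fit_ignition(d, baseline = NULL, screen_threshold = 1)
    est <- f$table[match(c("a", "b", "c"), f$table$variable), ]
    abs(est$B - beta) <= 1.96 * est$SE
  })
  expect_gte(mean(hits), 0.90)  # ~95% nominal, allow Monte-Carlo slack
})

test_that("perfect separation raises a diagnostic error", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  d <- data.frame(ignited = rep(0:1, each = 30), x = x)
  # glm itself warns about saturated probabilities on the way
  expect_error(suppressWarnings(fit_ignition(d, baseline = NULL)),
               "separation")
})

test_that("pseudo-R2 formulas match direct arithmetic", {
  expect_equal(pseudo_r2(-10, -10, 50)$cox_snell_r2, 0)
  expect_equal(pseudo_r2(-10, -10, 50)$nagelkerke_r2, 0)
  expect_equal(pseudo_r2(-1.386, -0.693, 2)$cox_snell_r2,
               1 - exp(-0.693), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    L1 <- -runif(1, 1, 50); L0 <- L1 - runif(1, 0, 30); n <- sample(5:500, 1)
    pr <- pseudo_r2(L0, L1, n)
    expect_gte(pr$nagelkerke_r2, pr$cox_snell_r2)
  }
  expect_error(pseudo_r2(-2, -1, 0), "positive")
})

test_that("AUC equals the brute-force pairwise-win probability", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    wins <- 0
    for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
    wins / (length(pos) * length(neg))
  }
  set.seed(77)
  for (i in 1:5) {
    n <- sample(20:500, 1)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    s <- round(rnorm(n, l), 1)  # rounding forces ties
    expect_equal(roc_auc(s, l), brute(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  l <- rbinom(300, 1, 0.5)
  s <- rnorm(300, l * 0.8)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
})

test_that("ignition surface behaves as the inverse-logit of the predictor", {
  L <- make_landscape(10, 10)
  wd <- make_weather_day()
  flat <- ignition_model(c(`(Intercept)` = 0, slope = 0))
  expect_true(all(ignition_surface(flat, L, wd) == 0.5))
  # masked cells are zeroed
  msk <- matrix(TRUE, 10, 10); msk[1, ] <- FALSE
  s <- ignition_surface(flat, L, wd, mask = msk)
  expect_true(all(s[1, ] == 0) && all(s[-1, ] == 0.5))
  # negative rh coefficient: drier day, higher probability everywhere
  m <- ignition_model(c(`(Intercept)` = -2, rh = -0.1))
  dry <- ignition_surface(m, L, make_weather_day(rh = 30))
  wet <- ignition_surface(m, L, make_weather_day(rh = 90))
  expect_true(all(dry > wet))
  expect_error(ignition_surface(ignition_model(c(nope = 1)), L, wd),
               "missing")
})

test_that("fitted surface recovers the generative surface (rank correlation)", {
  w <- shared_world()
  set.seed(6)
  occ <- build_occurrence_sample(w$history, w$landscape, w$weather)
  fit <- fit_ignition(occ)
  truth <- ignition_model(w$cfg$true_ignition)
  wd <- w$weather[50, ]
  s_fit <- ignition_surface(fit, w$landscape, wd)
  s_true <- ignition_surface(truth, w$landscape, wd)
  expect_gt(stats::cor(as.vector(s_fit), as.vector(s_true),
                       method = "spearman"), 0.9)
})
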