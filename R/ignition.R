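# Ignition-occurrence analysis: pseudo-absence sampling, collinearity
# screening, the binary logistic fit and its diagnostics, and daily
# ignition-probability surfaces.

#' Mean nearest-neighbour distance of a point set
#'
#' @param points Two-column matrix or data frame of planar coordinates in
#'   metres.
#' @return Mean over points of the distance to the nearest other point (m).
#' @export
mean_nn_distance <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Sample non-ignition (pseudo-absence) points
#'
#' Rejection sampling: cells are proposed uniformly over the burnable mask
#' and accepted if their centre lies at least `min_dist` from every
#' ignition. The default exclusion radius is the ignitions' mean
#' nearest-neighbour distance, so pseudo-absences avoid the immediate
#' neighbourhood of observed fires.
#'
#' @param ignitions Two-column matrix/data frame of ignition coordinates
#'   (m), same planar system as the landscape (lower-left origin).
#' @param mask Logical matrix of candidate (burnable) cells.
#' @param cell_size Cell size in metres.
#' @param n Number of points to return.
#' @param min_dist Exclusion radius in metres.
#' @param max_tries Proposal cap before declaring the constraint infeasible.
#' @return Data frame with `row`, `col`, `x`, `y` of the accepted points.
#' @export
sample_nonignitions <- function(ignitions, mask, cell_size, n,
                                min_dist = mean_nn_distance(ignitions),
                                max_tries = 1000L * n) {
  ign <- as.matrix(ignitions)
  nr <- nrow(mask)
  open <- which(mask)
  if (!length(open)) stop("empty mask")
  got_r <- integer(0); got_c <- integer(0)
  tries <- 0L
  batch <- max(64L, 4L * n)
  while (length(got_r) < n) {
    if (tries >= max_tries)
      stop("could not place ", n, " non-ignition points at min_dist = ",
           round(min_dist), " m after ", tries,
           " proposals; mask too small for the exclusion radius")
    k <- min(batch, max_tries - tries)
    cand <- open[sample.int(length(open), k, replace = TRUE)]
    tries <- tries + k
    r <- (cand - 1L) %% nr + 1L
    cc <- (cand - 1L) %/% nr + 1L
    x <- (cc - 0.5) * cell_size
    y <- (nr - r + 0.5) * cell_size
    if (min_dist > 0) {
      d2min <- rep(Inf, k)
      for (i in seq_len(nrow(ign)))
        d2min <- pmin(d2min, (x - ign[i, 1])^2 + (y - ign[i, 2])^2)
      keep <- d2min >= min_dist^2
    } else keep <- rep(TRUE, k)
    got_r <- c(got_r, r[keep]); got_c <- c(got_c, cc[keep])
  }
  got_r <- got_r[seq_len(n)]; got_c <- got_c[seq_len(n)]
  data.frame(row = got_r, col = got_c,
             x = (got_c - 0.5) * cell_size,
             y = (nr - got_r + 0.5) * cell_size)
}

#' Screen covariates for pairwise collinearity
#'
#' Greedy pass over all pairs with `|Pearson r| > threshold` in descending
#' `|r|`, dropping the lower-priority member of each offending pair until
#' no retained pair exceeds the threshold. Constant columns (undefined
#' correlation) are excluded up front with a warning.
#'
#' @param x Data frame or matrix of numeric covariates.
#' @param threshold Absolute-correlation threshold (default 0.4).
#' @param priority Numeric vector, one value per column; in an offending
#'   pair the column with the smaller priority is dropped (default: later
#'   columns have lower priority).
#' @return List with `retained` (column names), `dropped` (data frame of
#'   `dropped`, `against`, `r`) and `constant` (names of excluded constant
#'   columns).
#' @export
screen_collinearity <- function(x, threshold = 0.4, priority = NULL) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 covariates to screen")
  if (is.null(priority)) priority <- rev(seq_len(ncol(x)))
  stopifnot(length(priority) == ncol(x))
  names(priority) <- names(x)
  sds <- vapply(x, stats::sd, 0)
  const <- names(x)[sds == 0 | is.na(sds)]
  if (length(const))
    warning("constant column(s) excluded (correlation undefined): ",
            paste(const, collapse = ", "))
  keep <- setdiff(names(x), const)
  dropped <- data.frame(dropped = character(0), against = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    if (length(keep) < 2L) break
    cm <- stats::cor(x[keep])
    cm[!upper.tri(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1L, ]
    r <- cm[worst[1L], worst[2L]]
    # perfect collinearity is dropped whatever the threshold
    if (abs(r) <= threshold && abs(r) < 1 - 1e-12) break
    pair <- keep[worst]
    out <- pair[which.min(priority[pair])]
    dropped <- rbind(dropped, data.frame(
      dropped = out, against = setdiff(pair, out), r = r,
      stringsAsFactors = FALSE))
    keep <- setdiff(keep, out)
  }
  list(retained = keep, dropped = dropped, constant = const)
}

#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted 1/2 (mid-ranks).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cox & Snell and Nagelkerke pseudo-R-squared
#'
#' `CS = 1 - exp(2 * (L0 - L1) / n)`; `Nagelkerke = CS / (1 - exp(2 * L0 / n))`,
#' i.e. Cox & Snell rescaled by its attainable maximum.
#'
#' @param L0 Log-likelihood of the intercept-only model.
#' @param L1 Log-likelihood of the fitted model.
#' @param n Number of observations.
#' @return List with `cox_snell_r2` and `nagelkerke_r2`.
#' @export
pseudo_r2 <- function(L0, L1, n) {
  if (n <= 0) stop("n must be positive")
  cs <- 1 - exp(2 * (L0 - L1) / n)
  list(cox_snell_r2 = cs, nagelkerke_r2 = cs / (1 - exp(2 * L0 / n)))
}

# Covariate layers offered to the occurrence model, by factor group.
.occurrence_covariates <- function() {
  c("prop_pine", "prop_fir", "prop_broadleaf", "prop_others",
    "dominant_age", "elevation", "slope", "aspect",
    "precip", "t_avg", "rh",
    "pop_density", "dist_road", "dist_settlement")
}

# Landscape layer values at given cells, as a data frame.
.cell_covars <- function(landscape, rows, cols) {
  idx <- cbind(rows, cols)
  layers <- c("prop_pine", "prop_fir", "prop_broadleaf", "prop_others",
              "dominant_age", "elevation", "slope", "aspect",
              "pop_density", "dist_road", "dist_settlement")
  out <- lapply(layers, function(nm) landscape[[nm]][idx])
  names(out) <- layers
  as.data.frame(out)
}

#' Build the ignition/non-ignition occurrence sample
#'
#' One row per ignition (label 1) with the landscape covariates of its cell
#' and the weather of its date, plus `n_nonignitions` pseudo-absence rows
#' (label 0) sampled with [sample_nonignitions()] and paired with a
#' uniformly random archive day each (the non-ignition day).
#'
#' @param catalogue Fire catalogue data frame (`row`, `col`, `date`).
#' @param landscape A `fire_landscape`.
#' @param weather Weather archive covering the catalogue dates.
#' @param n_nonignitions Number of pseudo-absences (default: same as the
#'   number of ignitions).
#' @param min_dist Exclusion radius in metres (default: the ignitions'
#'   mean nearest-neighbour distance).
#' @return Data frame with column `ignited` (0/1) and the 14 candidate
#'   covariates (fuel, topography, weather, human activity).
#' @export
build_occurrence_sample <- function(catalogue, landscape, weather,
                                    n_nonignitions = nrow(catalogue),
                                    min_dist = NULL) {
  if (!nrow(catalogue)) stop("empty fire catalogue")
  cs <- landscape$cell_size
  nr <- landscape$n_rows
  ign_xy <- cbind((catalogue$col - 0.5) * cs,
                  (nr - catalogue$row + 0.5) * cs)
  if (is.null(min_dist)) min_dist <- mean_nn_distance(ign_xy)
  widx <- match(catalogue$date, weather$date)
  if (anyNA(widx)) stop("catalogue dates missing from the weather archive")
  pos <- cbind(.cell_covars(landscape, catalogue$row, catalogue$col),
               weather[widx, c("precip", "t_avg", "rh")])
  non <- sample_nonignitions(ign_xy, landscape$mask, cs, n_nonignitions,
                             min_dist = min_dist)
  nidx <- sample.int(nrow(weather), n_nonignitions, replace = TRUE)
  neg <- cbind(.cell_covars(landscape, non$row, non$col),
               weather[nidx, c("precip", "t_avg", "rh")])
  out <- rbind(cbind(ignited = 1L, pos), cbind(ignited = 0L, neg))
  rownames(out) <- NULL
  out[c("ignited", .occurrence_covariates())]
}

#' Fit the binary logistic ignition-occurrence model
#'
#' Drops the baseline fuel proportion (perfectly collinear with the other
#' three), screens the remaining covariates for pairwise `|r| >`
#' `screen_threshold` (retention priority: larger absolute point-biserial
#' association with the label), then fits a maximum-likelihood logistic
#' regression by IRLS. Reports per-variable coefficient, standard error,
#' Wald chi-square, p-value and odds ratio, plus Cox & Snell and Nagelkerke
#' pseudo-R2 and ROC-AUC.
#'
#' @param sample Occurrence sample from [build_occurrence_sample()] (or any
#'   data frame with a 0/1 label column and numeric covariates).
#' @param label Name of the label column.
#' @param baseline Fuel column excluded as the reference group (`NULL` to
#'   keep all).
#' @param screen_threshold Collinearity threshold passed to
#'   [screen_collinearity()].
#' @return An object of class `ignition_fit`: coefficient `table`
#'   (B, SE, Wald, Sig, ExpB), `diagnostics` (pseudo-R2s, AUC), the screen
#'   report, log-likelihoods `L0`/`L1`, `n`, and the underlying `glm`.
#' @export
fit_ignition <- function(sample, label = "ignited", baseline = "prop_others",
                         screen_threshold = 0.4) {
  y <- sample[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  covars <- setdiff(names(sample), c(label, baseline))
  x <- sample[covars]
  if (anyNA(x) || anyNA(y)) stop("missing values in the occurrence sample")
  prio <- vapply(x, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(0)
    abs(stats::cor(v, y))
  }, 0)
  scr <- if (ncol(x) >= 2L) {
    screen_collinearity(x, threshold = screen_threshold, priority = prio)
  } else {
    list(retained = names(x),
         dropped = data.frame(dropped = character(0), against = character(0),
                              r = numeric(0)),
         constant = character(0))
  }
  dat <- cbind(.y = y, x[scr$retained])
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  if (max(abs(stats::coef(fit))) > 15)
    stop("separation detected: diverging coefficients (|B| > 15); ",
         "the classes are (quasi-)perfectly separable")
  sm <- summary(fit)$coefficients
  B <- sm[, 1]; SE <- sm[, 2]
  wald <- (B / SE)^2
  tab <- data.frame(
    variable = c("(Intercept)", scr$retained),
    B = unname(B), SE = unname(SE), Wald = unname(wald),
    Sig = unname(stats::pchisq(wald, 1L, lower.tail = FALSE)),
    ExpB = unname(exp(B)),
    stringsAsFactors = FALSE)
  n <- length(y)
  L1 <- -fit$deviance / 2
  L0 <- -fit$null.deviance / 2
  pr2 <- pseudo_r2(L0, L1, n)
  structure(list(
    table = tab,
    coefficients = stats::setNames(B, c("(Intercept)", scr$retained)),
    variables = scr$retained,
    screen = scr,
    baseline = baseline,
    L0 = L0, L1 = L1, n = n,
    diagnostics = list(cox_snell_r2 = pr2$cox_snell_r2,
                       nagelkerke_r2 = pr2$nagelkerke_r2,
                       auc = roc_auc(stats::fitted(fit), y)),
    glm = fit), class = "ignition_fit")
}

#' Construct an ignition model from known coefficients
#'
#' Builds an `ignition_fit` directly from a named log-odds coefficient
#' vector (with an optional `(Intercept)` entry). Used to define the *true*
#' generative ignition surface of a synthetic world, and for spread-model
#' experiments with pinned coefficients.
#'
#' @param coefficients Named numeric vector; names must be occurrence
#'   covariates, plus optionally `(Intercept)`.
#' @return An `ignition_fit` without data-dependent diagnostics.
#' @export
ignition_model <- function(coefficients) {
  vars <- setdiff(names(coefficients), "(Intercept)")
  if (!length(vars)) stop("need at least one covariate coefficient")
  if (!"(Intercept)" %in% names(coefficients))
    coefficients <- c(`(Intercept)` = 0, coefficients)
  structure(list(
    table = NULL,
    coefficients = coefficients[c("(Intercept)", vars)],
    variables = vars, screen = NULL, baseline = NULL,
    L0 = NA_real_, L1 = NA_real_, n = 0L,
    diagnostics = NULL, glm = NULL), class = "ignition_fit")
}

#' @export
coef.ignition_fit <- function(object, ...) object$coefficients

#' @export
print.ignition_fit <- function(x, ...) {
  cat("Binary logistic ignition-occurrence model\n")
  if (!is.null(x$table)) {
    tab <- x$table
    tab[-1] <- lapply(tab[-1], round, 3)
    print(tab, row.names = FALSE)
    d <- x$diagnostics
    cat(sprintf("n = %d; Cox & Snell R2 = %.3f; Nagelkerke R2 = %.3f; AUC = %.2f%%\n",
                x$n, d$cox_snell_r2, d$nagelkerke_r2, 100 * d$auc))
  } else {
    cat("(constructed from known coefficients)\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
summary.ignition_fit <- function(object, ...) {
  if (!is.null(object$screen) && nrow(object$screen$dropped)) {
    cat("Variables dropped by the |r| > 0.4 screen:\n")
    print(object$screen$dropped, row.names = FALSE)
  }
  print(object)
  invisible(object)
}

#' @export
predict.ignition_fit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  lp <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (v in object$variables) {
    if (is.null(newdata[[v]])) stop("covariate '", v, "' missing")
    lp <- lp + object$coefficients[[v]] * newdata[[v]]
  }
  if (type == "link") lp else stats::plogis(lp)
}

# Static (landscape-only) part of the linear predictor, cached once per
# fit x landscape pair so per-day surfaces cost one vectorised plogis.
.surface_static <- function(fit, landscape) {
  wvars <- intersect(fit$variables, c("precip", "t_avg", "rh", "t_max",
                                      "wind_max", "wind_dir"))
  svars <- setdiff(fit$variables, wvars)
  lp <- matrix(fit$coefficients[["(Intercept)"]],
               landscape$n_rows, landscape$n_cols)
  for (v in svars) {
    if (is.null(landscape[[v]])) stop("covariate layer '", v, "' missing")
    lp <- lp + fit$coefficients[[v]] * landscape[[v]]
  }
  list(static_lp = lp, weather_vars = wvars,
       weather_coefs = fit$coefficients[wvars])
}

.surface_from_static <- function(cache, weather_day, mask = NULL) {
  w <- 0
  for (v in cache$weather_vars) {
    val <- weather_day[[v]]
    if (is.null(val)) stop("weather variable '", v, "' missing")
    w <- w + cache$weather_coefs[[v]] * val
  }
  p <- stats::plogis(cache$static_lp + w)
  if (!is.null(mask)) p[!mask] <- 0
  p
}

#' Daily ignition-probability surface
#'
#' Inverse-logit of the fitted linear predictor evaluated on every cell,
#' combining the static landscape covariates with the day's weather;
#' non-burnable cells are masked to zero.
#'
#' @param fit An `ignition_fit`.
#' @param landscape A `fire_landscape`.
#' @param weather_day One-row weather data frame.
#' @param mask Logical matrix; defaults to the landscape's burnable mask.
#' @return Probability matrix in \[0, 1\].
#' @export
ignition_surface <- function(fit, landscape, weather_day,
                             mask = landscape$mask) {
  .surface_from_static(.surface_static(fit, landscape), weather_day, mask)
}
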