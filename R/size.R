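# Fire-size modelling: an ensemble of 10 random forests on random 2/3
# training subsamples, averaged permutation importance, and stochastic
# size draws (prediction + bootstrap residual) for the simulator's
# termination rule.

.size_covariates <- function() {
  c("prop_pine", "pop_density", "slope", "prop_broadleaf", "dist_road",
    "aspect", "dominant_age", "prop_fir", "dist_settlement",
    "wind_velocity", "rh", "t_max")
}

#' Assemble the fire-size sample
#'
#' One row per catalogue fire: the response `size_ha` plus the 12 size
#' covariates (fuel and stand attributes, topography, human activity, and
#' the fire day's maximum wind velocity, relative humidity and maximum
#' temperature).
#'
#' @inheritParams build_occurrence_sample
#' @return Data frame with `size_ha` and the 12 covariates.
#' @export
build_size_sample <- function(catalogue, landscape, weather) {
  if (!nrow(catalogue)) stop("empty fire catalogue")
  widx <- match(catalogue$date, weather$date)
  if (anyNA(widx)) stop("catalogue dates missing from the weather archive")
  covs <- .cell_covars(landscape, catalogue$row, catalogue$col)
  out <- cbind(size_ha = catalogue$size_ha,
               covs,
               wind_velocity = weather$wind_max[widx],
               rh = weather$rh[widx],
               t_max = weather$t_max[widx])
  rownames(out) <- NULL
  out[c("size_ha", .size_covariates())]
}

#' Tune the number of variables tried at each split
#'
#' Sweeps `mtry` over 1..p around the regression default `floor(p / 3)`
#' and returns the value minimising the out-of-bag mean squared error of a
#' single forest of `ntree` trees; ties go to the smaller `mtry`.
#'
#' @param sample Size sample (response in `response`, remaining numeric
#'   columns are predictors).
#' @param ntree Trees per candidate forest.
#' @param response Name of the response column.
#' @return The selected integer `mtry`.
#' @export
tune_mtry <- function(sample, ntree = 1000, response = "size_ha") {
  y <- sample[[response]]
  x <- sample[setdiff(names(sample), response)]
  if (nrow(x) < 30L) stop("need at least 30 rows to tune mtry")
  p <- ncol(x)
  grid <- seq_len(p)
  oob <- vapply(grid, function(m) {
    rf <- randomForest::randomForest(x, y, ntree = ntree, mtry = m)
    rf$mse[ntree]
  }, 0)
  grid[which.min(oob)]  # which.min already prefers the smaller index on ties
}

#' Fit the ensemble of random-forest fire-size models
#'
#' `n_models` forests, each trained on an independent random `train_frac`
#' subsample (e.g. 150 of a ~225-fire catalogue) with the remaining rows
#' held out. Held-out residuals (observed - predicted, ha) are pooled
#' across models to describe the random error of the size prediction;
#' variance explained is `1 - MSE_holdout / Var(y_holdout)` averaged over
#' models; permutation importance (%IncMSE) is averaged over models.
#'
#' @param sample Size sample from [build_size_sample()].
#' @param mtry Variables tried per split; default `floor(p / 3)`. Use
#'   [tune_mtry()] to optimise it.
#' @param ntree Trees per forest.
#' @param n_models Ensemble size.
#' @param train_frac Training fraction in (0, 1).
#' @param response Name of the response column.
#' @return Object of class `size_ensemble`: fitted `models`, pooled
#'   holdout `residuals`, `importance` table (averaged %IncMSE,
#'   descending), `variance_explained`, `mtry`, `ntree`, and the training
#'   response range.
#' @export
fit_size_ensemble <- function(sample, mtry = NULL, ntree = 1000,
                              n_models = 10L, train_frac = 2 / 3,
                              response = "size_ha") {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly in (0, 1)")
  y <- sample[[response]]
  if (is.null(y)) stop("response column '", response, "' not found")
  if (any(y <= 0)) stop("fire sizes must be positive")
  x <- sample[setdiff(names(sample), response)]
  if (anyNA(x)) stop("missing covariates in the size sample")
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  n_train <- max(2L, round(train_frac * n))
  if (n_train >= n) stop("train_frac leaves no holdout rows")
  models <- vector("list", n_models)
  res <- numeric(0)
  ve <- numeric(n_models)
  imp <- matrix(0, p, n_models, dimnames = list(names(x), NULL))
  for (m in seq_len(n_models)) {
    tr <- sample.int(n, n_train)
    rf <- randomForest::randomForest(x[tr, ], y[tr], ntree = ntree,
                                     mtry = mtry, importance = TRUE)
    pred <- stats::predict(rf, x[-tr, ])
    r <- y[-tr] - pred
    res <- c(res, r)
    ve[m] <- 1 - mean(r^2) / stats::var(y[-tr])
    imp[, m] <- randomForest::importance(rf, type = 1L)[names(x), 1L]
    models[[m]] <- rf
  }
  avg <- sort(rowMeans(imp), decreasing = TRUE)
  structure(list(
    models = models,
    residuals = res,
    importance = data.frame(variable = names(avg), avg_inc_mse = unname(avg),
                            stringsAsFactors = FALSE),
    variance_explained = mean(ve),
    mtry = mtry, ntree = ntree, n_models = n_models,
    train_frac = train_frac,
    y_range = range(y), n = n), class = "size_ensemble")
}

#' @export
print.size_ensemble <- function(x, ...) {
  cat(sprintf(
    "Fire-size ensemble: %d random forests (ntree = %d, mtry = %d)\n",
    x$n_models, x$ntree, x$mtry))
  cat(sprintf("  trained on %d fires (%.0f%% subsamples); variance explained = %.2f%%\n",
              x$n, 100 * x$train_frac, 100 * x$variance_explained))
  cat("  top importance (Avg %IncMSE):\n")
  top <- utils::head(x$importance, 5L)
  cat(paste(sprintf("    %-18s %8.4f", top$variable, top$avg_inc_mse),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Averaged permutation importance of the ensemble
#'
#' @param ensemble A `size_ensemble`.
#' @return Data frame `variable`, `avg_inc_mse` sorted descending.
#' @export
ensemble_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "size_ensemble"))
  ensemble$importance
}

#' Pooled holdout residuals of the ensemble
#'
#' @param object A `size_ensemble`.
#' @param ... Unused.
#' @return Numeric vector of observed - predicted sizes (ha) on the
#'   held-out third of each member model.
#' @export
residuals.size_ensemble <- function(object, ...) object$residuals

#' Predict fire size
#'
#' Mean of the member-forest predictions, floored at zero.
#'
#' @param object A `size_ensemble`.
#' @param newdata Data frame with the 12 size covariates.
#' @param ... Unused.
#' @return Predicted sizes (ha).
#' @export
predict.size_ensemble <- function(object, newdata, ...) {
  vars <- rownames(randomForest::importance(object$models[[1L]]))
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  preds <- vapply(object$models,
                  function(m) as.numeric(stats::predict(m, newdata[vars])),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  pmax(rowMeans(preds), 0)
}

#' Draw stochastic fire sizes
#'
#' Ensemble prediction plus one bootstrap draw from the pooled holdout
#' residual pool per row, clamped below at `floor` (negative draws are
#' clamped, not redrawn, unless `redraw = TRUE`).
#'
#' @param ensemble A `size_ensemble`.
#' @param newdata Covariate rows.
#' @param floor Minimum returned size (ha); default 0.3, the smallest
#'   observable fire.
#' @param redraw If `TRUE`, draws whose total falls below `floor` are
#'   redrawn (up to 100 attempts) instead of clamped.
#' @return Sizes in ha, one per row of `newdata`.
#' @export
draw_stochastic_size <- function(ensemble, newdata, floor = 0.3,
                                 redraw = FALSE) {
  if (!length(ensemble$residuals)) stop("empty residual pool")
  pred <- predict(ensemble, newdata)
  n <- length(pred)
  out <- pred + sample(ensemble$residuals, n, replace = TRUE)
  if (redraw) {
    for (i in seq_len(100L)) {
      low <- out < floor
      if (!any(low)) break
      out[low] <- pred[low] + sample(ensemble$residuals, sum(low),
                                     replace = TRUE)
    }
  }
  pmax(out, floor)
}
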