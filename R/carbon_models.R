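#' Specification of a carbon density model
#'
#' The three model families used for pixelwise carbon density regression,
#' with the training hyperparameters fixed by the study protocol:
#' random forest (`rf`: 100 trees, maximum depth 5, minimum node size to
#' split 3, all predictors tried at each split, RNG state 42), decision tree
#' (`dt`: maximum depth 4, minimum split size 3, no complexity pruning, RNG
#' state 42), and multiple linear regression (`mlr`: ordinary least squares
#' `y = b0 + b1 x1 + ... + bn xn`). Data are split 7:3 into training and
#' test sets by simple random sampling.
#'
#' @param kind `"rf"`, `"dt"` or `"mlr"`.
#' @param predictor_names character vector of predictor (vegetation index)
#'   names.
#' @param split_fraction training fraction (default 0.7).
#' @param split_seed RNG seed for the train/test split.
#' @param hyper optional overrides of the defaults listed above.
#' @return a `carbon_model_spec` object.
#' @export
carbon_model_spec <- function(kind = c("rf", "dt", "mlr"), predictor_names,
                              split_fraction = 0.7, split_seed = 42,
                              hyper = list()) {
  kind <- match.arg(kind)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("'split_fraction' must be in (0, 1)")
  defaults <- switch(kind,
    rf = list(trees = 100L, max_depth = 5L, min_samples_split = 3L, seed = 42L),
    dt = list(max_depth = 4L, min_samples_split = 3L, seed = 42L),
    mlr = list())
  hyper <- utils::modifyList(defaults, hyper)
  structure(list(kind = kind, predictor_names = as.character(predictor_names),
                 split_fraction = split_fraction, split_seed = split_seed,
                 hyper = hyper),
            class = "carbon_model_spec")
}

#' Random 7:3 train/test split
#'
#' Simple random sampling without replacement; the training set has
#' `ceiling(fraction * n)` rows, deterministic for a fixed seed.
#'
#' @param n number of samples (or a data.frame, whose row count is used).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_data <- function(n, fraction = 0.7, seed = 42) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 5L) stop("at least 5 samples are required to split")
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  n_train <- as.integer(ceiling(fraction * n))
  train <- sort(with_seed(seed, sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit a carbon density model
#'
#' Trains the family requested by the spec on the full supplied data (use
#' [split_data()] beforehand to hold out a test set). `mlr` is ordinary
#' least squares; `rf` is a regression forest ([ranger::ranger()]) and `dt`
#' a regression tree ([rpart::rpart()]) honouring the spec's
#' hyperparameters. Training is deterministic given the spec seeds.
#'
#' @param spec a [carbon_model_spec].
#' @param X data.frame containing at least the spec's predictor columns; no
#'   missing values.
#' @param y numeric response (carbon density, t/ha).
#' @return a `fitted_carbon_model` with elements `spec`, `fit`,
#'   `training_metrics`.
#' @export
fit_carbon_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "carbon_model_spec"))
  X <- as.data.frame(X)
  missing <- setdiff(spec$predictor_names, names(X))
  if (length(missing))
    stop(sprintf("predictor column(s) missing: %s",
                 paste(missing, collapse = ", ")))
  X <- X[, spec$predictor_names, drop = FALSE]
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed in fitting")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  dat <- cbind(X, .carbon = y)
  fit <- switch(spec$kind,
    mlr = {
      m <- stats::lm(stats::reformulate(spec$predictor_names,
                                        response = ".carbon"), data = dat)
      if (m$rank < length(spec$predictor_names) + 1L)
        stop("rank-deficient design: predictors are exactly collinear")
      m
    },
    rf = ranger::ranger(
      stats::reformulate(spec$predictor_names, response = ".carbon"),
      data = dat, num.trees = spec$hyper$trees,
      max.depth = spec$hyper$max_depth,
      min.node.size = spec$hyper$min_samples_split,
      mtry = length(spec$predictor_names),
      seed = spec$hyper$seed, num.threads = 1L),
    dt = with_seed(spec$hyper$seed, rpart::rpart(
      stats::reformulate(spec$predictor_names, response = ".carbon"),
      data = dat, method = "anova",
      control = rpart::rpart.control(maxdepth = spec$hyper$max_depth,
                                     minsplit = spec$hyper$min_samples_split,
                                     minbucket = 1L, cp = 0,
                                     xval = 0L))))
  out <- structure(list(spec = spec, fit = fit, training_metrics = NULL),
                   class = "fitted_carbon_model")
  # rRMSE (and thus the metric row) is undefined when mean(y) = 0
  out$training_metrics <- tryCatch(evaluate_metrics(y, predict_carbon(out, X)),
                                   error = function(e) NULL)
  out
}

#' Predict carbon density for new samples
#'
#' @param model a `fitted_carbon_model`.
#' @param newdata data.frame with the spec's predictor columns.
#' @return numeric vector of predicted density (t/ha), unfloored.
#' @export
predict_carbon <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_carbon_model"))
  newdata <- as.data.frame(newdata)[, model$spec$predictor_names,
                                    drop = FALSE]
  switch(model$spec$kind,
    mlr = unname(stats::predict(model$fit, newdata = newdata)),
    dt = unname(stats::predict(model$fit, newdata = newdata)),
    rf = stats::predict(model$fit, data = newdata,
                        num.threads = 1L)$predictions)
}

#' Accuracy metrics for density predictions
#'
#' The five evaluation statistics used throughout the pipeline, for
#' observed `y` and predicted `yhat`:
#' \itemize{
#' \item `r2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`
#' \item `rmse = sqrt(mean((y - yhat)^2))` (t/ha)
#' \item `rrmse = rmse / ybar` (dimensionless; see Details)
#' \item `mae = mean(|y - yhat|)` (t/ha)
#' \item `mbe = mean(y - yhat)` (t/ha; positive = underprediction)
#' }
#'
#' @details The relative RMSE is the ratio of the RMSE to the mean observed
#' value. An alternative printed form, `sqrt(mean((y - yhat)^2) / ybar)`, is
#' dimensionally inconsistent (its value depends on the measurement unit)
#' but is available via `rrmse_form = "printed"` for comparison against
#' sources that used it.
#'
#' @param y observed values, length >= 2.
#' @param yhat predicted values, same length.
#' @param rrmse_form `"ratio"` (default) or `"printed"`.
#' @return one-row data.frame `r2, rmse, rrmse, mae, mbe, n`.
#' @export
evaluate_metrics <- function(y, yhat, rrmse_form = c("ratio", "printed")) {
  rrmse_form <- match.arg(rrmse_form)
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("at least 2 samples are required")
  n <- length(y)
  e <- y - yhat
  ybar <- mean(y)
  sse <- sum(e^2)
  sst <- sum((y - ybar)^2)
  rmse <- sqrt(sse / n)
  rrmse <- if (rrmse_form == "ratio") {
    if (ybar == 0) stop("rRMSE undefined: mean observed value is zero")
    rmse / ybar
  } else sqrt(sse / n / ybar)
  data.frame(r2 = 1 - sse / sst, rmse = rmse, rrmse = rrmse,
             mae = mean(abs(e)), mbe = mean(e), n = n)
}

#' Fit, hold out, and evaluate in one call
#'
#' Applies the spec's 7:3 split, fits on the training rows, and evaluates on
#' both subsets.
#'
#' @inheritParams fit_carbon_model
#' @return a `fitted_carbon_model` with `training_metrics`, `test_metrics`
#'   and the `split` indices attached.
#' @export
train_carbon_model <- function(spec, X, y) {
  X <- as.data.frame(X)
  sp <- split_data(nrow(X), fraction = spec$split_fraction,
                   seed = spec$split_seed)
  m <- fit_carbon_model(spec, X[sp$train, , drop = FALSE], y[sp$train])
  m$test_metrics <- evaluate_metrics(y[sp$test],
                                     predict_carbon(m, X[sp$test, , drop = FALSE]))
  m$split <- sp
  m
}

#' Predict a carbon density map
#'
#' Applies a fitted model pixelwise over co-gridded vegetation index
#' rasters. Pixels outside the mask, or with any masked predictor, are
#' nodata. Negative predictions are floored at zero (densities are
#' physical); the number of floored pixels is reported as an attribute.
#'
#' @param model a `fitted_carbon_model`.
#' @param vis named list of single-band [raster_stack]s covering the spec's
#'   predictors.
#' @param mask logical matrix (TRUE = predict) on the same grid, or `NULL`
#'   to predict wherever all predictors are valid.
#' @return single-band [raster_stack] `"density"` (t/ha) with attribute
#'   `n_floored`.
#' @export
predict_density_map <- function(model, vis, mask = NULL) {
  stopifnot(inherits(model, "fitted_carbon_model"))
  need <- model$spec$predictor_names
  missing <- setdiff(need, names(vis))
  if (length(missing))
    stop(sprintf("predictor raster(s) missing: %s",
                 paste(missing, collapse = ", ")))
  ref <- vis[[need[1]]]
  mats <- lapply(need, function(nm) {
    stop_unless_cogridded(ref, vis[[nm]])
    band(vis[[nm]], band_names(vis[[nm]])[1])
  })
  d <- dim(ref)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d)) stop("mask grid does not match the predictors")
  valid <- mask & Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  out <- matrix(NA_real_, d[1], d[2])
  idx <- which(valid)
  n_floored <- 0L
  if (length(idx)) {
    newdata <- stats::setNames(
      as.data.frame(lapply(mats, function(m) m[idx])), need)
    pred <- predict_carbon(model, newdata)
    n_floored <- sum(pred < 0)
    out[idx] <- pmax(pred, 0)
  }
  r <- raster_stack(list(density = out), res_m = ref$res_m,
                    origin = ref$origin, crs = ref$crs)
  attr(r, "n_floored") <- n_floored
  r
}
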