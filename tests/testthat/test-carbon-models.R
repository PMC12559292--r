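test_that("the 7:3 split partitions deterministically with a ceiling train size", {
  sp <- split_data(10, fraction = 0.7, seed = 1)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_data(10, fraction = 0.7, seed = 1))
  expect_false(identical(sp$train, split_data(10, seed = 2)$train))
  expect_length(split_data(11, 0.7, 1)$train, 8L)   # ceiling(7.7)
  expect_error(split_data(4), "at least 5")
  expect_error(split_data(10, fraction = 1.2), "in \\(0, 1\\)")
})

test_that("MLR recovers exact coefficients without noise and true ones within 3 SE", {
  x <- seq(0, 10, length.out = 50)
  spec <- carbon_model_spec("mlr", "x")
  m <- fit_carbon_model(spec, data.frame(x = x), 2 + 3 * x)
  expect_equal(unname(coef(m$fit)), c(2, 3), tolerance = 1e-9)
  # noisy recovery at n = 200 with known sigma
  set.seed(77)
  x2 <- runif(200, 0, 10)
  y2 <- 2 + 3 * x2 + rnorm(200, sd = 1.5)
  m2 <- fit_carbon_model(spec, data.frame(x = x2), y2)
  se <- summary(m2$fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(m2$fit) - c(2, 3)) <= 3 * se))
  # exact collinearity is a rank error
  expect_error(
    fit_carbon_model(carbon_model_spec("mlr", c("a", "b")),
                     data.frame(a = x, b = 2 * x), 1 + x),
    "rank-deficient")
})

test_that("decision trees honor the depth constraint", {
  set.seed(21)
  X <- data.frame(a = runif(300), b = runif(300))
  y <- sin(6 * X$a) + X$b^2 + rnorm(300, sd = 0.05)
  m <- fit_carbon_model(carbon_model_spec("dt", c("a", "b")), X, y)
  depths <- floor(log2(as.integer(
    rownames(m$fit$frame)[m$fit$frame$var == "<leaf>"])))
  expect_lte(max(depths), 4L)
})

test_that("RF and DT refits with fixed seeds are run-to-run identical", {
  set.seed(22)
  X <- data.frame(a = runif(120), b = runif(120))
  y <- 3 * X$a - X$b + rnorm(120, sd = 0.1)
  for (kind in c("rf", "dt")) {
    spec <- carbon_model_spec(kind, c("a", "b"))
    p1 <- predict_carbon(fit_carbon_model(spec, X, y), X)
    p2 <- predict_carbon(fit_carbon_model(spec, X, y), X)
    expect_identical(p1, p2)
  }
})

test_that("evaluation metrics match their definitions exactly", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  m <- evaluate_metrics(y, yhat)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-12)
  expect_equal(m$mbe, -1 / 3, tolerance = 1e-12)
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  expect_equal(m$rrmse, sqrt(1 / 3) / 2, tolerance = 1e-12)
  # perfect fit and mean-only predictor
  perfect <- evaluate_metrics(y, y)
  expect_equal(unlist(perfect[c("r2", "rmse", "rrmse", "mae", "mbe")]),
               c(r2 = 1, rmse = 0, rrmse = 0, mae = 0, mbe = 0))
  expect_equal(evaluate_metrics(y, rep(mean(y), 3))$r2, 0)
  expect_error(evaluate_metrics(1:3, 1:4), "equal length")
  # the printed rRMSE variant stays available
  expect_equal(evaluate_metrics(y, yhat, rrmse_form = "printed")$rrmse,
               sqrt((1 / 3) / 2), tolerance = 1e-12)
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n, 20, 6); yhat <- y + rnorm(n, 0, 3)
    m <- evaluate_metrics(y, yhat)
    sse <- 0; sab <- 0; sbe <- 0
    for (j in seq_len(n)) {
      sse <- sse + (y[j] - yhat[j])^2
      sab <- sab + abs(y[j] - yhat[j])
      sbe <- sbe + (y[j] - yhat[j])
    }
    expect_equal(m$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(sse / n), tolerance = 1e-12)
    expect_equal(m$rrmse, sqrt(sse / n) / mean(y), tolerance = 1e-12)
    expect_equal(m$mae, sab / n, tolerance = 1e-12)
    expect_equal(m$mbe, sbe / n, tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("MLR predictions are equivariant under predictor rescaling", {
  set.seed(9)
  X <- data.frame(a = runif(80, 0, 1), b = runif(80, 0, 1))
  y <- 5 + 2 * X$a - 3 * X$b + rnorm(80, sd = 0.2)
  spec <- carbon_model_spec("mlr", c("a", "b"))
  m1 <- fit_carbon_model(spec, X, y)
  Xs <- data.frame(a = 10 * X$a, b = X$b - 2)
  m2 <- fit_carbon_model(spec, Xs, y)
  expect_equal(predict_carbon(m1, X), predict_carbon(m2, Xs),
               tolerance = 1e-9)
})

test_that("density maps respect masks, floor negatives and report them", {
  grid <- function(v) raster_stack(matrix(v, 6, 6), res_m = 30)
  x <- matrix(seq(-1, 1, length.out = 36), 6, 6)
  vis <- list(x = raster_stack(x, res_m = 30))
  # intercept-only behaviour via a zero-slope fit
  m0 <- fit_carbon_model(carbon_model_spec("mlr", "x"),
                         data.frame(x = 1:10), rep(5, 10))
  mask <- matrix(TRUE, 6, 6); mask[1, ] <- FALSE
  map <- predict_density_map(m0, vis, mask)
  expect_true(all(is.na(band(map, "density")[1, ])))
  expect_equal(band(map, "density")[-1, ], matrix(5, 5, 6), tolerance = 1e-9)
  # a negative-going fit gets floored, with a count
  mneg <- fit_carbon_model(carbon_model_spec("mlr", "x"),
                           data.frame(x = c(-1, 0, 1, 2, 3)),
                           c(-10, -5, 0, 5, 10))
  map2 <- predict_density_map(mneg, vis, NULL)
  expect_true(all(band(map2, "density") >= 0))
  expect_gt(attr(map2, "n_floored"), 0)
  # empty mask -> all nodata
  map3 <- predict_density_map(m0, vis, matrix(FALSE, 6, 6))
  expect_true(all(is.na(band(map3, "density"))))
  expect_error(predict_density_map(m0, list(), NULL), "missing")
})

test_that("a random forest recovers the density surface on a clean scene", {
  sc <- cached("clean_scene",
               generate_scene(scene_config(extent_px = c(90, 90), seed = 5,
                                           sensor_noise_sd = 0,
                                           vi_signal_r = 0.99)))
  vis <- compute_vis(sc$stack_10m, c("NDVI", "SAVI", "gNDVI"), "s2a")
  f <- sc$forest_mask_10m
  den <- band(sc$true_density_10m, "density")
  idx <- which(f)
  set.seed(2)
  tr <- sample(idx, 400)
  X <- data.frame(NDVI = band(vis$NDVI, "NDVI")[tr],
                  SAVI = band(vis$SAVI, "SAVI")[tr],
                  gNDVI = band(vis$gNDVI, "gNDVI")[tr])
  m <- fit_carbon_model(carbon_model_spec("rf", names(X)), X, den[tr])
  map <- predict_density_map(m, vis, f)
  r2 <- evaluate_metrics(den[idx], band(map, "density")[idx])$r2
  expect_gte(r2, 0.8)
})
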