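#' Fit per-class Gaussian models for maximum-likelihood classification
#'
#' Estimates a mean vector and covariance matrix per land-cover class from
#' training pixels. Singular covariances (e.g. identical training samples)
#' are ridge-regularized by adding `1e-8 * trace / n_bands` to the diagonal,
#' and the regularization is reported.
#'
#' @param training named list: class -> matrix of band vectors (rows =
#'   pixels, columns = bands). Every class needs at least `n_bands + 1`
#'   samples.
#' @param priors named prior probabilities (default equal).
#' @return named list of class models (`mean`, `cov`, `prior`,
#'   `regularized`), class `mlc_model`.
#' @export
fit_mlc <- function(training, priors = NULL) {
  if (!length(training) || is.null(names(training)))
    stop("'training' must be a named list of class sample matrices")
  nb <- ncol(as.matrix(training[[1]]))
  if (is.null(priors))
    priors <- stats::setNames(rep(1 / length(training), length(training)),
                              names(training))
  models <- lapply(names(training), function(cl) {
    x <- as.matrix(training[[cl]])
    if (nrow(x) < nb + 1L)
      stop(sprintf("class '%s' has %d samples; need at least %d",
                   cl, nrow(x), nb + 1L))
    mu <- colMeans(x)
    S <- stats::cov(x)
    reg <- FALSE
    ridge <- 1e-8 * max(sum(diag(S)), 1) / nb
    if (inherits(try(chol(S), silent = TRUE), "try-error")) {
      S <- S + diag(ridge, nb)
      reg <- TRUE
      warning(sprintf("singular covariance for class '%s'; ridge %g added",
                      cl, ridge))
    }
    list(mean = mu, cov = S, prior = priors[[cl]], regularized = reg)
  })
  structure(stats::setNames(models, names(training)), class = "mlc_model")
}

#' Classify a raster stack by maximum likelihood
#'
#' Assigns each pixel the class maximizing the Gaussian log-likelihood plus
#' log prior. Ties go to the lowest class index (the order of the fitted
#' model list). Pixels with any masked band are nodata.
#'
#' @param stack a [raster_stack] whose bands match the training bands (by
#'   count and order).
#' @param models an `mlc_model` from [fit_mlc()].
#' @return single-band [raster_stack] `"class"` of 1-based class indices,
#'   with the class names attached as attribute `labels`.
#' @export
classify_mlc <- function(stack, models) {
  stopifnot(inherits(models, "mlc_model"))
  nb <- length(models[[1]]$mean)
  if (length(stack$bands) != nb)
    stop(sprintf("stack has %d bands but the model was trained on %d",
                 length(stack$bands), nb))
  d <- dim(stack)
  X <- vapply(stack$bands, as.vector, numeric(d[1] * d[2]))
  ok <- stats::complete.cases(X)
  scores <- matrix(-Inf, sum(ok), length(models))
  Xok <- X[ok, , drop = FALSE]
  for (k in seq_along(models)) {
    m <- models[[k]]
    R <- chol(m$cov)
    z <- forwardsolve(t(R), t(Xok) - m$mean)
    scores[, k] <- -sum(log(diag(R))) - 0.5 * colSums(z^2) + log(m$prior)
  }
  # round away last-bit noise so exact ties resolve to the lowest index
  lab <- max.col(round(scores, 9), ties.method = "first")
  out <- rep(NA_real_, d[1] * d[2])
  out[ok] <- lab
  r <- raster_stack(list(class = matrix(out, d[1], d[2])),
                    res_m = stack$res_m, origin = stack$origin,
                    crs = stack$crs)
  attr(r, "labels") <- names(models)
  r
}

#' Confusion matrix, overall accuracy and Cohen's kappa
#'
#' @param pred,truth co-gridded categorical [raster_stack]s or label
#'   vectors/factors. Pixels where either is nodata are dropped.
#' @return list `matrix` (K x K counts, prediction in rows), `overall_accuracy`,
#'   `kappa`, `n`.
#' @export
confusion <- function(pred, truth) {
  as_labels <- function(x) {
    if (inherits(x, "raster_stack")) as.vector(band(x, band_names(x)[1]))
    else as.vector(x)
  }
  p <- as_labels(pred); t <- as_labels(truth)
  if (length(p) != length(t)) stop("pred and truth sizes differ")
  ok <- !is.na(p) & !is.na(t)
  p <- p[ok]; t <- t[ok]
  n <- length(p)
  if (n == 0L) stop("no jointly labelled pixels")
  lev <- sort(unique(c(p, t)))
  cm <- table(factor(p, levels = lev), factor(t, levels = lev))
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(matrix = cm, overall_accuracy = po, kappa = kappa, n = n)
}
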