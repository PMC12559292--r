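#' Geodetector factor detector
#'
#' Quantifies how much of the spatial variance of a continuous variable
#' (carbon density) a categorical stratification explains:
#' `q = 1 - sum(n_h * s2_h) / (n * s2)`, where `s2_h` is the population
#' variance within stratum `h` and `s2` the overall population variance.
#' `q = 0` means the strata explain nothing, `q = 1` that the variable is
#' constant within every stratum. Strata with fewer than 2 observations are
#' excluded and reported; a single usable stratum yields `q = 0` with a
#' flag.
#'
#' @param values numeric vector (or single-band [raster_stack]).
#' @param strata categorical vector / factor (or co-gridded categorical
#'   [raster_stack]).
#' @return a `q_result` list: `q`, `n`, `strata` (data.frame `stratum`,
#'   `n_h`, `mean_h`, `var_h`), `excluded_strata`, `flag`.
#' @export
factor_q <- function(values, strata) {
  v <- as_values(values); s <- as_values(strata)
  if (length(v) != length(s)) stop("values and strata sizes differ")
  ok <- !is.na(v) & !is.na(s)
  v <- v[ok]; s <- as.character(s[ok])
  nh <- table(s)
  excluded <- names(nh)[nh < 2L]
  keep <- !(s %in% excluded)
  v <- v[keep]; s <- s[keep]
  n <- length(v)
  flag <- NULL
  if (n < 2L || length(unique(s)) < 2L) {
    if (n >= 2L) flag <- "single stratum: q = 0 by convention"
    else flag <- "insufficient data"
    strata_tab <- if (n) data.frame(stratum = unique(s), n_h = n,
                                    mean_h = mean(v), var_h = pvar(v))
    else data.frame(stratum = character(0), n_h = integer(0),
                    mean_h = numeric(0), var_h = numeric(0))
    return(structure(list(q = 0, n = n, strata = strata_tab,
                          excluded_strata = excluded, flag = flag),
                     class = "q_result"))
  }
  gm <- tapply(v, s, mean)
  gv <- tapply(v, s, pvar)
  gn <- tapply(v, s, length)
  s2 <- pvar(v)
  q <- if (s2 == 0) 0 else 1 - sum(gn * gv) / (n * s2)
  structure(list(q = q, n = n,
                 strata = data.frame(stratum = names(gm),
                                     n_h = as.integer(gn),
                                     mean_h = as.numeric(gm),
                                     var_h = as.numeric(gv),
                                     stringsAsFactors = FALSE),
                 excluded_strata = excluded, flag = flag),
            class = "q_result")
}

pvar <- function(x) mean((x - mean(x))^2)   # population variance

as_values <- function(x) {
  if (inherits(x, "raster_stack")) as.vector(band(x, band_names(x)[1]))
  else if (is.factor(x)) as.character(x)
  else as.vector(x)
}

#' Geodetector interaction detector
#'
#' Computes the explanatory power of two stratifications jointly (on the
#' cross-classification of their labels) and categorizes the interaction by
#' comparing `q_AB` with `q_A`, `q_B`, their minimum, maximum and sum:
#' nonlinear weaken (`q_AB < min`), univariate weaken (`min <= q_AB <=
#' max`), bivariate enhance (`max < q_AB < q_A + q_B`), independent
#' (`q_AB = q_A + q_B` within tolerance), nonlinear enhance
#' (`q_AB > q_A + q_B`).
#'
#' @param values numeric vector (or single-band [raster_stack]).
#' @param strata_a,strata_b two stratifications (vectors, factors or
#'   co-gridded categorical [raster_stack]s).
#' @param tol tolerance for the `independent` category.
#' @return a `q_result` list with `q` (= `q_AB`), `q_a`, `q_b`, `category`,
#'   `n`, `flag`.
#' @export
interaction_q <- function(values, strata_a, strata_b, tol = 1e-9) {
  v <- as_values(values)
  a <- as_values(strata_a); b <- as_values(strata_b)
  if (length(v) != length(a) || length(v) != length(b))
    stop("values and strata sizes differ")
  ok <- !is.na(v) & !is.na(a) & !is.na(b)
  qa <- factor_q(v[ok], a[ok])
  qb <- factor_q(v[ok], b[ok])
  ab <- paste(a[ok], b[ok], sep = "\r")
  if (all(table(ab) < 2L))
    stop("all cross-strata are singletons; interaction undefined")
  qab <- factor_q(v[ok], ab)
  flag <- NULL
  if (length(unique(a[ok])) < 2L || length(unique(b[ok])) < 2L)
    flag <- "one factor is constant: q_AB degenerates to the other factor's q"
  lo <- min(qa$q, qb$q); hi <- max(qa$q, qb$q); sm <- qa$q + qb$q
  category <- if (qab$q > sm + tol) "nonlinear enhance"
  else if (abs(qab$q - sm) <= tol) "independent"
  else if (qab$q > hi + tol) "bivariate enhance"
  else if (qab$q >= lo - tol) "univariate weaken"
  else "nonlinear weaken"
  structure(list(q = qab$q, q_a = qa$q, q_b = qb$q, category = category,
                 n = qab$n, excluded_strata = qab$excluded_strata,
                 flag = flag),
            class = "q_result")
}

#' Discretize a continuous factor into strata
#'
#' Continuous covariates (elevation, temperature, GDP, ...) must be
#' stratified before geodetection. `"quantile"` gives classes of (near)
#' equal count; `"equal_interval"` splits the value range evenly. Empty
#' classes are merged away and reported.
#'
#' @param x numeric vector, matrix or single-band [raster_stack].
#' @param k number of classes (>= 2).
#' @param method `"quantile"` or `"equal_interval"`.
#' @return object of the same shape as `x` with integer class labels
#'   (1-based); attributes `breaks` and `n_merged` (classes dropped because
#'   they were empty or had collapsing breaks).
#' @export
discretize_continuous <- function(x, k, method = c("quantile",
                                                   "equal_interval")) {
  method <- match.arg(method)
  if (k < 2) stop("'k' must be >= 2")
  is_rs <- inherits(x, "raster_stack")
  v <- as_values(x)
  ok <- !is.na(v)
  vv <- v[ok]
  if (length(unique(vv)) == 1L) {
    out <- ifelse(is.na(v), NA_real_, 1)
    n_merged <- k - 1L
    br <- range(vv)
    warning("constant input: a single class was produced")
  } else {
    br <- if (method == "quantile")
      stats::quantile(vv, probs = seq(0, 1, length.out = k + 1), names = FALSE)
    else seq(min(vv), max(vv), length.out = k + 1)
    br <- unique(br)
    n_merged <- k + 1L - length(br)
    out <- rep(NA_real_, length(v))
    out[ok] <- findInterval(vv, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
  }
  res <- if (is_rs) {
    m <- matrix(out, dim(x)[1], dim(x)[2])
    raster_stack(list(stratum = m), res_m = x$res_m, origin = x$origin,
                 crs = x$crs)
  } else if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  attr(res, "breaks") <- br
  attr(res, "n_merged") <- n_merged
  res
}
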