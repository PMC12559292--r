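#' Pearson product-moment correlation with validation
#'
#' The screening statistic used throughout predictor selection:
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`.
#' Pairs with a missing value in either vector are dropped listwise.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs and
#'   neither constant.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y, method = "pearson")
}

#' Screen candidate predictors by correlation with the response
#'
#' Candidates are ranked by `|r|` (ties broken by their order in
#' `candidates`, i.e. registry order) and those with `|r| >= threshold` are
#' flagged selected. If none pass and `top_k` is set, the `top_k` strongest
#' are selected instead, so a model can always be built; if none pass and
#' `top_k` is unset, the selection is empty and a warning is raised.
#'
#' @param candidates named list or data.frame of candidate predictor vectors.
#' @param y response vector (plot or reference carbon density, t/ha).
#' @param threshold absolute-correlation selection threshold (default 0.5).
#' @param top_k optional cap / fallback count for the selection.
#' @return data.frame with columns `index`, `r`, `abs_r`, `n`, `rank`,
#'   `selected`, ordered by rank; attribute `selected` holds the selected
#'   names in rank order.
#' @export
screen_by_correlation <- function(candidates, y, threshold = 0.5,
                                  top_k = NULL) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L) stop("at least one candidate is required")
  r <- vapply(candidates, function(x) pearson_r(x, y), numeric(1))
  n <- vapply(candidates, function(x)
    sum(stats::complete.cases(x, y)), numeric(1))
  ord <- order(-abs(r), seq_along(r))  # registry order breaks ties
  rep <- data.frame(index = names(candidates)[ord], r = r[ord],
                    abs_r = abs(r)[ord], n = n[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rep$selected <- rep$abs_r >= threshold
  if (!is.null(top_k)) {
    if (!any(rep$selected)) rep$selected[seq_len(min(top_k, nrow(rep)))] <- TRUE
    else rep$selected[-seq_len(min(top_k, nrow(rep)))] <- FALSE
  } else if (!any(rep$selected)) {
    warning("no candidate reached the correlation threshold; empty selection")
  }
  attr(rep, "selected") <- rep$index[rep$selected]
  rep
}

#' Variance inflation factor filter
#'
#' Iteratively removes multicollinear predictors: each column's VIF is
#' `1 / (1 - R2_j)` where `R2_j` is the coefficient of determination from
#' regressing that column on all remaining columns; while the largest VIF
#' exceeds `limit` (default 10), that column is removed and the VIFs are
#' recomputed. Exactly collinear columns (auxiliary `R2_j = 1`) are removed
#' first, later-ranked column first, and recorded as `exact collinearity`.
#' A single remaining column has VIF 1 by convention.
#'
#' @param X data.frame or matrix of the selected predictors (rows are
#'   samples; more rows than columns).
#' @param limit VIF removal threshold.
#' @return list with `vif` (named vector for the retained columns),
#'   `removed` (data.frame `index`, `vif`, `reason` in removal order), and
#'   `X` (the retained matrix as a data.frame).
#' @export
vif_filter <- function(X, limit = 10) {
  X <- as.data.frame(X)
  if (ncol(X) < 1L) stop("at least one column is required")
  if (nrow(X) <= ncol(X))
    stop("VIF needs more rows than columns")
  removed <- data.frame(index = character(0), vif = numeric(0),
                        reason = character(0), stringsAsFactors = FALSE)
  one_vif <- function(j, D) {
    fit <- stats::lm(stats::reformulate(names(D)[-j], response = names(D)[j]),
                     data = D)
    # an exactly collinear column yields a perfect auxiliary fit; that is an
    # expected, handled case, so silence lm's perfect-fit warning
    r2 <- suppressWarnings(summary(fit))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (ncol(X) == 1L) {
      vifs <- stats::setNames(1, names(X))
      break
    }
    vifs <- vapply(seq_len(ncol(X)), one_vif, numeric(1), D = X)
    names(vifs) <- names(X)
    worst <- which.max(rev(vifs))          # prefer the later-ranked column
    worst <- ncol(X) + 1L - worst
    if (!is.finite(vifs[worst])) {
      removed <- rbind(removed, data.frame(index = names(X)[worst], vif = Inf,
                                           reason = "exact collinearity"))
      X[[worst]] <- NULL
    } else if (vifs[worst] > limit) {
      removed <- rbind(removed, data.frame(index = names(X)[worst],
                                           vif = vifs[worst],
                                           reason = "vif above limit"))
      X[[worst]] <- NULL
    } else break
  }
  list(vif = vifs, removed = removed, X = X)
}

#' Correlation screen followed by VIF filter
#'
#' Convenience wrapper producing the final modeling predictor set: listwise
#' deletion of incomplete rows, [screen_by_correlation()], then
#' [vif_filter()] on the selected columns.
#'
#' @inheritParams screen_by_correlation
#' @inheritParams vif_filter
#' @return list with `correlation` (screen report), `vif` (filter report or
#'   `NULL` when fewer than two indices were selected), and `selected`
#'   (character vector of final predictor names).
#' @export
select_predictors <- function(candidates, y, threshold = 0.5, top_k = 3,
                              limit = 10) {
  tab <- cbind(as.data.frame(candidates), .y = y)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  yy <- tab$.y; tab$.y <- NULL
  rep <- screen_by_correlation(tab, yy, threshold = threshold, top_k = top_k)
  sel <- attr(rep, "selected")
  vif <- NULL
  if (length(sel) >= 2L) {
    vif <- vif_filter(tab[, sel, drop = FALSE], limit = limit)
    sel <- names(vif$X)
  }
  list(correlation = rep, vif = vif, selected = sel)
}
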