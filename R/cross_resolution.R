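#' Mosaic per-class density predictions into a whole-forest map
#'
#' Each forest pixel takes the prediction of its own class; class masks must
#' be pairwise disjoint. The merged map's coverage is the union of the
#' masks.
#'
#' @param predictions named list of single-band [raster_stack]s, one per
#'   class (t/ha).
#' @param masks named list of logical matrices on the same grid, aligned
#'   with `predictions` by name.
#' @return list with `merged` (single-band [raster_stack] `"density"`),
#'   `predictions`, `masks`.
#' @export
mosaic_species <- function(predictions, masks) {
  if (!length(predictions) || is.null(names(predictions)))
    stop("'predictions' must be a named list")
  if (!setequal(names(predictions), names(masks)))
    stop("'masks' must align with 'predictions' by name")
  ref <- predictions[[1]]
  d <- dim(ref)
  cover <- matrix(0L, d[1], d[2])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d)) stop("mask grids differ")
    cover <- cover + masks[[nm]]
  }
  n_overlap <- sum(cover > 1L)
  if (n_overlap > 0L)
    stop(sprintf("class masks overlap on %d pixel(s)", n_overlap))
  merged <- matrix(NA_real_, d[1], d[2])
  for (nm in names(predictions)) {
    stop_unless_cogridded(ref, predictions[[nm]])
    p <- band(predictions[[nm]], band_names(predictions[[nm]])[1])
    merged[masks[[nm]]] <- p[masks[[nm]]]
  }
  list(merged = raster_stack(list(density = merged), res_m = ref$res_m,
                             origin = ref$origin, crs = ref$crs),
       predictions = predictions, masks = masks)
}

#' Aggregate a 10 m density mosaic to the nested 30 m grid
#'
#' Each 30 m cell takes the mean over its forest 10 m children
#' (`aggregate = "mean"`; `"nearest"` takes the central child instead). The
#' fraction of forest children is recorded per cell; cells with no forest
#' child are nodata. Requires exact 3x3 nesting.
#'
#' @param mosaic single-band [raster_stack] at 10 m (density t/ha, NA
#'   outside forest).
#' @param forest_mask logical matrix at 10 m; defaults to non-NA mosaic
#'   pixels.
#' @param method `"mean"` (default) or `"nearest"`.
#' @return list with `reference` (30 m density [raster_stack]) and
#'   `forest_fraction` (30 m [raster_stack] in `[0, 1]`).
#' @export
aggregate_to_30m <- function(mosaic, forest_mask = NULL,
                             method = c("mean", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(mosaic, "raster_stack"))
  if (mosaic$res_m * 3 != 30 && mosaic$res_m != 10)
    stop("mosaic must be on the 10 m grid")
  m <- band(mosaic, band_names(mosaic)[1])
  if (nrow(m) %% 3L || ncol(m) %% 3L)
    stop("10 m grid does not nest the 30 m grid exactly (extent not divisible by 3)")
  if (is.null(forest_mask)) forest_mask <- !is.na(m)
  if (!identical(dim(forest_mask), dim(m))) stop("forest mask grid differs")
  mm <- m
  mm[!forest_mask] <- NA_real_
  vals <- mm; vals[is.na(vals)] <- 0
  child_n <- block_mean_3x3((!is.na(mm)) * 9)      # forest children per cell
  total <- block_mean_3x3(vals) * 9
  ref <- if (method == "mean") {
    out <- total / child_n
    out[child_n == 0] <- NA_real_
    out
  } else {
    nr <- nrow(m); nc <- ncol(m)
    ctr <- mm[seq(2, nr, 3), seq(2, nc, 3), drop = FALSE]
    ctr[child_n == 0] <- NA_real_
    ctr
  }
  list(reference = raster_stack(list(density = ref), res_m = 30,
                                origin = mosaic$origin, crs = mosaic$crs),
       forest_fraction = raster_stack(list(fraction = child_n / 9),
                                      res_m = 30, origin = mosaic$origin,
                                      crs = mosaic$crs))
}

#' Approach 1: direct coarse-resolution carbon modeling
#'
#' Models plot-measured carbon density directly against coarse-resolution
#' (30 m) vegetation indices: indices are computed from the 30 m stack,
#' sampled at the plot centers, screened by correlation and VIF, a model of
#' the requested kind is trained on the 7:3 split, and density is predicted
#' over the forest extent.
#'
#' @param plot_densities data.frame from [plots_carbon_density()] (columns
#'   `carbon_density`, `x`, `y`).
#' @param stack_30m 3-band 30 m [raster_stack] (`b3`, `b4`, `b5`).
#' @param forest_mask_30m logical matrix at 30 m marking prediction cells.
#' @param kind model family (`"mlr"`, `"rf"`, `"dt"`).
#' @param candidates index names to consider (default: all `l8` registry
#'   indices).
#' @param threshold,top_k,vif_limit screening parameters (see
#'   [select_predictors()]).
#' @param split_seed seed of the 7:3 split.
#' @return list with `model` (`fitted_carbon_model`), `map` (density
#'   [raster_stack]), `selection`, `vis`.
#' @export
approach1 <- function(plot_densities, stack_30m, forest_mask_30m,
                      kind = "mlr", candidates = NULL, threshold = 0.5,
                      top_k = 3, vif_limit = 10, split_seed = 42) {
  if (is.null(candidates)) candidates <- names(vi_registry("l8"))
  vis <- compute_vis(stack_30m, candidates, sensor = "l8")
  vi_at_plots <- extract_vis_at_points(vis, plot_densities)
  sel <- select_predictors(vi_at_plots, plot_densities$carbon_density,
                           threshold = threshold, top_k = top_k,
                           limit = vif_limit)
  if (!length(sel$selected)) stop("no predictors selected")
  spec <- carbon_model_spec(kind, sel$selected, split_seed = split_seed)
  model <- train_carbon_model(spec, vi_at_plots,
                              plot_densities$carbon_density)
  map <- predict_density_map(model, vis, mask = forest_mask_30m)
  list(model = model, map = map, selection = sel, vis = vis)
}

#' Approach 2: cross-resolution reference transfer
#'
#' Fine-resolution per-class predictions, aggregated to the 30 m grid
#' ([aggregate_to_30m()]), serve as the training target for a
#' coarse-resolution model: eligible cells (forest fraction >= `min_forest_fraction`)
#' are subsampled, the 30 m vegetation indices are screened against the
#' reference values, a model is trained and density is predicted over the
#' eligible cells. The fitted model can be reapplied to another date's 30 m
#' indices (the historical back-casting use case).
#'
#' @param reference result of [aggregate_to_30m()] (or a single-band 30 m
#'   [raster_stack]).
#' @param stack_30m 3-band 30 m [raster_stack].
#' @param forest_fraction 30 m [raster_stack] of forest fractions (taken
#'   from `reference` when it is an [aggregate_to_30m()] result).
#' @param min_forest_fraction eligibility threshold for training/prediction
#'   cells (default 0.5, limiting mixed-pixel dilution).
#' @param sample_n number of training cells subsampled from the eligible
#'   set (`NULL` = all).
#' @param seed subsampling seed.
#' @inheritParams approach1
#' @return list with `model`, `map`, `selection`, `vis`, `eligible_mask`.
#' @export
approach2 <- function(reference, stack_30m, forest_fraction = NULL,
                      kind = "mlr", candidates = NULL, threshold = 0.5,
                      top_k = 3, vif_limit = 10,
                      min_forest_fraction = 0.5, sample_n = NULL,
                      seed = 42) {
  if (is.list(reference) && !inherits(reference, "raster_stack")) {
    forest_fraction <- forest_fraction %||% reference$forest_fraction
    reference <- reference$reference
  }
  ref <- band(reference, band_names(reference)[1])
  frac <- if (is.null(forest_fraction)) (!is.na(ref)) * 1
          else band(forest_fraction, band_names(forest_fraction)[1])
  eligible <- !is.na(ref) & frac >= min_forest_fraction
  idx <- which(eligible)
  if (length(idx) < 10L)
    stop("fewer than 10 eligible 30 m cells for reference modeling")
  if (is.null(candidates)) candidates <- names(vi_registry("l8"))
  vis <- compute_vis(stack_30m, candidates, sensor = "l8")
  train_idx <- if (!is.null(sample_n) && sample_n < length(idx))
    with_seed(seed, sample(idx, sample_n)) else idx
  vi_cells <- as.data.frame(lapply(vis, function(v)
    band(v, band_names(v)[1])[train_idx]))
  sel <- select_predictors(vi_cells, ref[train_idx], threshold = threshold,
                           top_k = top_k, limit = vif_limit)
  if (!length(sel$selected)) stop("no predictors selected")
  spec <- carbon_model_spec(kind, sel$selected, split_seed = seed)
  keep <- stats::complete.cases(vi_cells[, sel$selected, drop = FALSE],
                                ref[train_idx])
  model <- fit_carbon_model(spec, vi_cells[keep, , drop = FALSE],
                            ref[train_idx][keep])
  map <- predict_density_map(model, vis, mask = eligible)
  list(model = model, map = map, selection = sel, vis = vis,
       eligible_mask = eligible)
}

#' Classify pixelwise discrepancy between two density maps
#'
#' Relative discrepancy `|estimate - reference| / reference` per pixel,
#' classed as `minor` (< 30%), `moderate` (30-60%, endpoints included) or
#' `substantial` (> 60%). Pixels where either map is nodata, or the
#' reference is zero, are excluded and counted.
#'
#' @param estimate,reference co-gridded single-band [raster_stack]s (t/ha).
#' @return list with `class_map` ([raster_stack], 1 = minor, 2 = moderate,
#'   3 = substantial), `fractions` (named percentages over compared pixels,
#'   summing to 100), `n_compared`, `n_excluded`.
#' @export
discrepancy_classify <- function(estimate, reference) {
  stop_unless_cogridded(estimate, reference)
  e <- band(estimate, band_names(estimate)[1])
  r <- band(reference, band_names(reference)[1])
  ok <- !is.na(e) & !is.na(r) & r != 0
  rel <- abs(e - r) / r
  cls <- matrix(NA_real_, nrow(e), ncol(e))
  cls[ok & rel < 0.3] <- 1
  cls[ok & rel >= 0.3 & rel <= 0.6] <- 2
  cls[ok & rel > 0.6] <- 3
  n_comp <- sum(ok)
  if (n_comp == 0L) stop("no comparable pixels")
  fr <- vapply(1:3, function(k) 100 * sum(cls == k, na.rm = TRUE) / n_comp,
               numeric(1))
  names(fr) <- c("minor", "moderate", "substantial")
  list(class_map = raster_stack(list(class = cls), res_m = estimate$res_m,
                                origin = estimate$origin,
                                crs = estimate$crs),
       fractions = fr, n_compared = n_comp,
       n_excluded = sum((is.na(e) | is.na(r) | r == 0) &
                          !(is.na(e) & is.na(r))))
}

#' Total carbon storage of a density map
#'
#' `total = sum(density * pixel_area)` over valid pixels; pixel area follows
#' the resolution (10 m -> 0.01 ha, 30 m -> 0.09 ha).
#'
#' @param density single-band [raster_stack] in t/ha.
#' @param weights optional matrix of per-pixel area weights in `[0, 1]`
#'   (e.g. forest fraction of 30 m cells), defaulting to 1.
#' @return list `total_t`, `mean_density`, `min_density`, `max_density`,
#'   `area_ha`, `n_pixels`.
#' @export
total_storage <- function(density, weights = NULL) {
  stopifnot(inherits(density, "raster_stack"))
  m <- band(density, band_names(density)[1])
  area_px <- density$res_m^2 / 1e4
  if (is.null(weights)) weights <- matrix(1, nrow(m), ncol(m))
  ok <- !is.na(m)
  if (!any(ok)) {
    warning("all-nodata density map; total storage is 0")
    return(list(total_t = 0, mean_density = NA_real_, min_density = NA_real_,
                max_density = NA_real_, area_ha = 0, n_pixels = 0L))
  }
  w <- weights[ok]
  list(total_t = sum(m[ok] * w * area_px),
       mean_density = mean(m[ok]),
       min_density = min(m[ok]),
       max_density = max(m[ok]),
       area_ha = sum(w) * area_px,
       n_pixels = sum(ok))
}

#' Storage composition and temporal change
#'
#' `storage_composition()` turns per-class totals into percentage shares of
#' their sum. `storage_change()` reports the between-date difference in t
#' and in percent of the earlier total.
#'
#' @param class_totals named non-negative numeric vector of per-class totals
#'   (t).
#' @return `storage_composition()`: data.frame `class, total_t, share_pct`
#'   (shares sum to 100) plus a `whole` attribute with the summed total.
#' @export
storage_composition <- function(class_totals) {
  if (any(class_totals < 0)) stop("totals must be non-negative")
  tot <- sum(class_totals)
  if (tot <= 0) stop("total storage must be positive for composition")
  data.frame(class = names(class_totals),
             total_t = as.numeric(class_totals),
             share_pct = 100 * as.numeric(class_totals) / tot,
             stringsAsFactors = FALSE) -> out
  attr(out, "whole_total_t") <- tot
  out
}

#' @rdname storage_composition
#' @param earlier_t,later_t totals (t) at the earlier and later date.
#' @return `storage_change()`: list `change_t`, `change_pct`.
#' @export
storage_change <- function(earlier_t, later_t) {
  if (earlier_t < 0 || later_t < 0) stop("totals must be non-negative")
  if (earlier_t == 0) stop("percent change undefined for a zero baseline")
  list(change_t = later_t - earlier_t,
       change_pct = 100 * (later_t - earlier_t) / earlier_t)
}

#' Combined storage report
#'
#' Per-class totals and densities, whole-forest total, composition, and
#' (optionally) change against an earlier date's total.
#'
#' @param class_maps named list of single-band density [raster_stack]s, one
#'   per class.
#' @param earlier_total_t optional earlier-date whole-forest total (t).
#' @return list `per_class` (data.frame), `whole_total_t`, `composition`,
#'   `change` (or `NULL`).
#' @export
storage_report <- function(class_maps, earlier_total_t = NULL) {
  per <- lapply(class_maps, total_storage)
  tab <- data.frame(class = names(per),
                    total_t = vapply(per, `[[`, numeric(1), "total_t"),
                    mean_density = vapply(per, `[[`, numeric(1), "mean_density"),
                    min_density = vapply(per, `[[`, numeric(1), "min_density"),
                    max_density = vapply(per, `[[`, numeric(1), "max_density"),
                    stringsAsFactors = FALSE)
  comp <- storage_composition(stats::setNames(tab$total_t, tab$class))
  list(per_class = tab, whole_total_t = attr(comp, "whole_total_t"),
       composition = comp,
       change = if (!is.null(earlier_total_t))
         storage_change(earlier_total_t, attr(comp, "whole_total_t")))
}
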