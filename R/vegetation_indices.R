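#' Vegetation index registry for the two sensor layouts
#'
#' Band-arithmetic definitions for both band layouts used by the pipeline:
#' `s2a` (Sentinel-2A style, bands b2 blue, b3 green, b4 red, b5 red edge,
#' b8 NIR, b8A narrow NIR, all at 10 m) and `l8` (Landsat-8 OLI style, bands
#' b3 green, b4 red, b5 NIR at 30 m).
#'
#' Definitions (per sensor, `NIR`/`red`/`green`/`blue` resolve to the
#' sensor's bands):
#' \itemize{
#' \item NDVI = (NIR - red)/(NIR + red)
#' \item gNDVI = (NIR - green)/(NIR + green)
#' \item SAVI = (NIR - red)(1 + L)/(NIR + red + L), soil factor `L`
#' \item DVI = NIR - red
#' \item SR = NIR/red
#' \item RDVI = (NIR - red)/sqrt(NIR + red)
#' \item NDWI = (green - NIR)/(green + NIR)
#' \item gCI = NIR/green - 1
#' \item EVI = 2.5 (NIR - red)/(NIR + 6 red - 7.5 blue + 1); on the 3-band
#'   `l8` layout the two-band form 2.5 (NIR - red)/(NIR + 2.4 red + 1) is
#'   used instead
#' \item reNDVI = (b8A - b5)/(b8A + b5), reSR = b8A/b5, ARVI =
#'   (NIR - (2 red - blue))/(NIR + (2 red - blue)): `s2a` only
#' }
#' NDWI, EVI and gCI are standard published definitions adopted where the
#' source registry names an index without a formula. The printed SAVI for
#' the `l8` layout references a panchromatic band; here SAVI is always the
#' NIR/red form of the sensor (the panchromatic reading is treated as a
#' typo).
#'
#' @param sensor `"s2a"` or `"l8"`.
#' @param L SAVI soil adjustment factor (dimensionless; 0.5 default).
#' @return named list of index definitions; each has `required_bands` and an
#'   evaluation function of the band list.
#' @export
vi_registry <- function(sensor = c("s2a", "l8"), L = 0.5) {
  sensor <- match.arg(sensor)
  b <- if (sensor == "s2a")
    list(blue = "b2", green = "b3", red = "b4", re = "b5",
         nir = "b8", nnir = "b8A")
  else list(green = "b3", red = "b4", nir = "b5")
  def <- function(req, f) list(required_bands = unname(unlist(req)), fun = f)
  safe_div <- function(num, den) {
    out <- num / den
    out[abs(den) < 1e-12] <- NA_real_
    out
  }
  reg <- list(
    NDVI = def(b[c("nir", "red")], function(x)
      safe_div(x[[b$nir]] - x[[b$red]], x[[b$nir]] + x[[b$red]])),
    gNDVI = def(b[c("nir", "green")], function(x)
      safe_div(x[[b$nir]] - x[[b$green]], x[[b$nir]] + x[[b$green]])),
    SAVI = def(b[c("nir", "red")], function(x)
      safe_div((x[[b$nir]] - x[[b$red]]) * (1 + L),
               x[[b$nir]] + x[[b$red]] + L)),
    DVI = def(b[c("nir", "red")], function(x) x[[b$nir]] - x[[b$red]]),
    SR = def(b[c("nir", "red")], function(x)
      safe_div(x[[b$nir]], x[[b$red]])),
    RDVI = def(b[c("nir", "red")], function(x) {
      s <- x[[b$nir]] + x[[b$red]]
      out <- (x[[b$nir]] - x[[b$red]]) / sqrt(s)
      out[s <= 1e-12] <- NA_real_
      out
    }),
    NDWI = def(b[c("green", "nir")], function(x)
      safe_div(x[[b$green]] - x[[b$nir]], x[[b$green]] + x[[b$nir]])),
    gCI = def(b[c("nir", "green")], function(x)
      safe_div(x[[b$nir]], x[[b$green]]) - 1)
  )
  if (sensor == "s2a") {
    reg$EVI <- def(b[c("nir", "red", "blue")], function(x)
      safe_div(2.5 * (x[[b$nir]] - x[[b$red]]),
               x[[b$nir]] + 6 * x[[b$red]] - 7.5 * x[[b$blue]] + 1))
    reg$reNDVI <- def(b[c("nnir", "re")], function(x)
      safe_div(x[[b$nnir]] - x[[b$re]], x[[b$nnir]] + x[[b$re]]))
    reg$reSR <- def(b[c("nnir", "re")], function(x)
      safe_div(x[[b$nnir]], x[[b$re]]))
    reg$ARVI <- def(b[c("nir", "red", "blue")], function(x) {
      rb <- 2 * x[[b$red]] - x[[b$blue]]
      safe_div(x[[b$nir]] - rb, x[[b$nir]] + rb)
    })
  } else {
    reg$EVI <- def(b[c("nir", "red")], function(x)
      safe_div(2.5 * (x[[b$nir]] - x[[b$red]]),
               x[[b$nir]] + 2.4 * x[[b$red]] + 1))
  }
  reg
}

#' Compute a vegetation index raster
#'
#' Evaluates a registered index pixelwise over a reflectance stack. Pixels
#' with a degenerate formula (zero denominator) are masked in the output, as
#' are pixels masked in any required input band.
#'
#' @param stack a [raster_stack] holding the sensor's reflectance bands.
#' @param index index name present in [vi_registry()] for the sensor.
#' @param sensor `"s2a"` or `"l8"`.
#' @param L SAVI soil factor.
#' @return a single-band [raster_stack] named after the index.
#' @examples
#' s <- raster_stack(list(b4 = matrix(0.1, 2, 2), b3 = matrix(0.1, 2, 2),
#'                        b5 = matrix(0.5, 2, 2)), res_m = 30)
#' band(compute_vi(s, "NDVI", sensor = "l8"), "NDVI")[1, 1]
#' @export
compute_vi <- function(stack, index, sensor = c("s2a", "l8"), L = 0.5) {
  sensor <- match.arg(sensor)
  reg <- vi_registry(sensor, L = L)
  if (!index %in% names(reg))
    stop(sprintf("unknown index '%s' for sensor '%s'", index, sensor))
  d <- reg[[index]]
  missing <- setdiff(d$required_bands, band_names(stack))
  if (length(missing))
    stop(sprintf("missing band(s) for %s: %s", index,
                 paste(missing, collapse = ", ")))
  vals <- d$fun(stack$bands)
  out <- stats::setNames(list(vals), index)
  raster_stack(out, res_m = stack$res_m, origin = stack$origin,
               crs = stack$crs)
}

#' Compute several vegetation indices at once
#'
#' @inheritParams compute_vi
#' @param indices character vector of registry names; defaults to every
#'   index defined for the sensor.
#' @return named list of single-band [raster_stack]s.
#' @export
compute_vis <- function(stack, indices = NULL, sensor = c("s2a", "l8"),
                        L = 0.5) {
  sensor <- match.arg(sensor)
  if (is.null(indices)) indices <- names(vi_registry(sensor, L = L))
  stats::setNames(lapply(indices, function(i)
    compute_vi(stack, i, sensor = sensor, L = L)), indices)
}

#' Extract vegetation indices at plot locations
#'
#' @param vis named list of single-band [raster_stack]s (one per index).
#' @param points data.frame with `x`, `y`.
#' @return data.frame, one column per index.
#' @export
extract_vis_at_points <- function(vis, points) {
  as.data.frame(lapply(vis, function(v) extract_at_points(v, points)))
}
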