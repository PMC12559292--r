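#' Georeferenced multiband raster stack
#'
#' Lightweight in-memory container for co-registered reflectance or density
#' grids. Bands are plain numeric matrices (rows = north-to-south, columns =
#' west-to-east); `NA` marks nodata. The georeference is a north-up affine
#' transform given by the coordinate of the top-left corner of the top-left
#' pixel and a square pixel size in metres. Pixels are areas: pixel
#' `[i, j]` covers the half-open square
#' `[x0 + (j-1) res, x0 + j res) x (y0 - i res, y0 - (i-1) res]`.
#'
#' @param bands named list of numeric matrices, all the same dimension, or a
#'   single matrix (stored under the name `"value"`).
#' @param res_m pixel size in metres (10 or 30 for the two sensor layouts,
#'   but any positive value is accepted).
#' @param origin numeric length-2, `c(x0, y0)`: top-left corner coordinate.
#' @param crs free-text coordinate reference tag; stacks are only ever
#'   combined when the tags match.
#' @return an object of class `raster_stack`.
#' @examples
#' r <- raster_stack(matrix(1:12, 3, 4), res_m = 10)
#' dim(r)
#' band_names(r)
#' @export
raster_stack <- function(bands, res_m, origin = c(0, 0), crs = "local") {
  if (is.matrix(bands)) bands <- list(value = bands)
  if (!is.list(bands) || length(bands) == 0L)
    stop("'bands' must be a matrix or a non-empty named list of matrices")
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("all bands must be named")
  dims <- lapply(bands, dim)
  if (any(!vapply(bands, is.matrix, logical(1))))
    stop("every band must be a matrix")
  d1 <- dims[[1]]
  if (any(!vapply(dims, identical, logical(1), d1)))
    stop("all bands must share the same dimensions")
  if (!is.numeric(res_m) || length(res_m) != 1L || res_m <= 0)
    stop("'res_m' must be a single positive number")
  structure(
    list(bands = lapply(bands, function(b) {b <- as.matrix(b); storage.mode(b) <- "double"; b}),
         res_m = as.numeric(res_m),
         origin = as.numeric(origin),
         crs = as.character(crs)),
    class = "raster_stack")
}

#' @export
dim.raster_stack <- function(x) dim(x$bands[[1]])

#' Band access and names
#' @param x a [raster_stack].
#' @param name band name.
#' @return `band()`: the band matrix; `band_names()`: character vector.
#' @export
band <- function(x, name) {
  stopifnot(inherits(x, "raster_stack"))
  if (!name %in% names(x$bands))
    stop(sprintf("band '%s' not present (have: %s)", name,
                 paste(names(x$bands), collapse = ", ")))
  x$bands[[name]]
}

#' @rdname band
#' @export
band_names <- function(x) names(x$bands)

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("raster_stack: %d x %d @ %g m, bands: %s, crs: %s\n",
              d[1], d[2], x$res_m, paste(band_names(x), collapse = ", "),
              x$crs))
  invisible(x)
}

# shared grid check used before any pixelwise combination
stop_unless_cogridded <- function(a, b) {
  if (!identical(dim(a), dim(b)) || a$res_m != b$res_m ||
      !isTRUE(all.equal(a$origin, b$origin)) || a$crs != b$crs)
    stop("rasters are not co-gridded (dimension, resolution, origin or crs differ)")
  invisible(TRUE)
}

#' Look up raster values at point coordinates
#'
#' Containment-based lookup (no interpolation): each point takes the value of
#' the pixel whose area contains it. Masked (`NA`) pixels yield `NA`.
#'
#' @param x a [raster_stack] or a single matrix band of one.
#' @param points data.frame or matrix with columns `x` and `y` in the stack's
#'   CRS.
#' @param band_name which band to read when `x` holds several.
#' @return numeric vector, one value per point.
#' @export
extract_at_points <- function(x, points, band_name = band_names(x)[1]) {
  stopifnot(inherits(x, "raster_stack"))
  m <- band(x, band_name)
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) {
    if (ncol(pts) >= 2) names(pts)[1:2] <- c("x", "y")
    else stop("'points' needs columns x and y")
  }
  ij <- point_to_cell(x, pts$x, pts$y)
  bad <- which(is.na(ij[, 1]))
  if (length(bad))
    stop(sprintf("point(s) outside raster extent at index: %s",
                 paste(bad, collapse = ", ")))
  m[cbind(ij[, 1], ij[, 2])]
}

# (row, col) of the pixel containing each point; NA row where outside.
point_to_cell <- function(r, x, y) {
  nr <- dim(r)[1]; nc <- dim(r)[2]
  col <- floor((x - r$origin[1]) / r$res_m) + 1L
  row <- floor((r$origin[2] - y) / r$res_m) + 1L
  # top and left edges are inclusive per the half-open pixel convention
  out <- row < 1L | row > nr | col < 1L | col > nc
  row[out] <- NA_integer_; col[out] <- NA_integer_
  cbind(row = row, col = col)
}

# centre coordinate of pixel (i, j)
cell_center <- function(r, i, j) {
  cbind(x = r$origin[1] + (j - 0.5) * r$res_m,
        y = r$origin[2] - (i - 0.5) * r$res_m)
}

#' Crop a raster stack to a rectangular pixel window
#'
#' @param x a [raster_stack].
#' @param rows,cols integer ranges of pixel indices to keep (contiguous).
#' @return a [raster_stack] with an adjusted origin.
#' @export
crop_stack <- function(x, rows, cols) {
  stopifnot(inherits(x, "raster_stack"))
  rows <- sort(unique(as.integer(rows))); cols <- sort(unique(as.integer(cols)))
  if (any(diff(rows) != 1L) || any(diff(cols) != 1L))
    stop("'rows' and 'cols' must be contiguous index ranges")
  d <- dim(x)
  if (rows[1] < 1L || rows[length(rows)] > d[1] ||
      cols[1] < 1L || cols[length(cols)] > d[2])
    stop("crop window exceeds raster extent")
  raster_stack(lapply(x$bands, function(b) b[rows, cols, drop = FALSE]),
               res_m = x$res_m,
               origin = c(x$origin[1] + (cols[1] - 1L) * x$res_m,
                          x$origin[2] - (rows[1] - 1L) * x$res_m),
               crs = x$crs)
}

#' Read and write single-band rasters as ESRI ASCII grid text files
#'
#' Plain-text exchange format for single-band grids (header of
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` followed by rows of
#' numbers, north row first). Continuous rasters default to nodata -9999,
#' categorical to 0.
#'
#' @param x a [raster_stack]; the band `band_name` is written.
#' @param path file path.
#' @param band_name band to write.
#' @param nodata value standing in for `NA` in the file.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a single-band [raster_stack].
#' @export
write_ascii_grid <- function(x, path, band_name = band_names(x)[1],
                             nodata = -9999) {
  stopifnot(inherits(x, "raster_stack"))
  m <- band(x, band_name)
  d <- dim(m)
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", x$origin[1]),
           sprintf("yllcorner %.10g", x$origin[2] - d[1] * x$res_m),
           sprintf("cellsize %.10g", x$res_m),
           sprintf("NODATA_value %.10g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (length(ln) != 1L) stop(sprintf("missing '%s' in ASCII grid header", key))
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nd <- val("NODATA_value")
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(nums) != nr * nc) stop("ASCII grid body does not match header size")
  m <- matrix(nums, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nd] <- NA_real_
  raster_stack(m, res_m = cs, origin = c(xll, yll + nr * cs))
}
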