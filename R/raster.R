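#' Lightweight single-band raster on a metric grid
#'
#' A minimal in-memory raster: a numeric matrix of cell values on a regular
#' square grid in a projected (metric) coordinate system. The first matrix
#' index runs along x (easting), the second along y (northing), both
#' increasing; cell centers sit at \code{xmin + (ix - 0.5) * res}.
#'
#' @param values numeric matrix, first dimension x, second dimension y
#' @param res cell size in meters
#' @param xmin,ymin coordinates of the lower-left corner of the grid (meters)
#' @return an object of class \code{bm_raster}
#' @export
bm_raster <- function(values, res, xmin = 0, ymin = 0) {
  stopifnot(is.matrix(values), is.numeric(res), res > 0)
  structure(list(values = values, res = res, xmin = xmin, ymin = ymin,
                 nx = nrow(values), ny = ncol(values)),
            class = "bm_raster")
}

#' @export
print.bm_raster <- function(x, ...) {
  cat(sprintf("<bm_raster> %d x %d cells, %.6g m resolution, origin (%.6g, %.6g)\n",
              x$nx, x$ny, x$res, x$xmin, x$ymin))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: min %.6g, mean %.6g, max %.6g\n",
                             min(v), mean(v), max(v)))
  invisible(x)
}

#' @export
dim.bm_raster <- function(x) c(x$nx, x$ny)

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + r$nx * r$res,
    ymin = r$ymin, ymax = r$ymin + r$ny * r$res)
}

#' Map coordinates to cell indices
#'
#' @param r a \code{bm_raster} (or anything carrying nx/ny/res/xmin/ymin)
#' @param x,y coordinate vectors (meters)
#' @param what label used in the error message for out-of-extent points
#' @return list with integer vectors \code{ix}, \code{iy}
#' @keywords internal
cell_index <- function(r, x, y, what = "point") {
  ix <- floor((x - r$xmin) / r$res) + 1L
  iy <- floor((y - r$ymin) / r$res) + 1L
  bad <- which(ix < 1L | ix > r$nx | iy < 1L | iy > r$ny | !is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop(sprintf("%s outside raster extent: first offending %s at (%.1f, %.1f)",
                 what, what, x[bad[1]], y[bad[1]]))
  }
  list(ix = ix, iy = iy)
}

#' Look up raster values at coordinates (nearest cell)
#'
#' @inheritParams cell_index
#' @return numeric vector of cell values
#' @export
raster_lookup <- function(r, x, y, what = "point") {
  ci <- cell_index(r, x, y, what = what)
  r$values[cbind(ci$ix, ci$iy)]
}

#' Test whether coordinates fall inside the raster extent
#' @inheritParams cell_index
#' @return logical vector
#' @export
raster_inside <- function(r, x, y) {
  ext <- raster_extent(r)
  x >= ext["xmin"] & x < ext["xmax"] & y >= ext["ymin"] & y < ext["ymax"]
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced single-band raster format (.asc): a six-line
#' header followed by rows of cell values from north to south.
#'
#' @param r a \code{bm_raster}
#' @param path output file
#' @param digits significant digits for cell values
#' @export
write_asc <- function(r, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$nx),
    sprintf("nrows %d", r$ny),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$res),
    "NODATA_value -9999"), con)
  v <- r$values
  v[!is.finite(v)] <- -9999
  # rows north -> south; within a row west -> east
  for (iy in r$ny:1) {
    writeLines(paste(signif(v[, iy], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by \code{write_asc}
#' @param path file path
#' @return a \code{bm_raster}
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- as.numeric(kv[, 2]); names(val) <- tolower(kv[, 1])
  nx <- as.integer(val[["ncols"]]); ny <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = nx, ncol = ny)  # filled row-by-row from north
  m <- m[, ny:1, drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA_real_
  bm_raster(m, res = val[["cellsize"]], xmin = val[["xllcorner"]], ymin = val[["yllcorner"]])
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a reproducible per-stage seed below 2^31 from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
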