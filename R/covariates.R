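#' Terrain ruggedness index (3x3 moving window)
#'
#' Riley's TRI: per cell, the square root of the summed squared elevation
#' differences between the cell and its 8 neighbors. Edge cells use the
#' neighbors that exist. Invariant to adding a constant to the DEM and scales
#' linearly with a DEM scaling.
#'
#' @param dem a \code{bm_raster} of elevations (meters)
#' @return a \code{bm_raster} of TRI values
#' @export
compute_tri <- function(dem) {
  stopifnot(inherits(dem, "bm_raster"))
  bm_raster(compute_tri_matrix(dem$values), res = dem$res, xmin = dem$xmin, ymin = dem$ymin)
}

compute_tri_matrix <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  acc <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    d <- z[xs[okx], ys[oky], drop = FALSE] - z[okx, oky, drop = FALSE]
    acc[okx, oky] <- acc[okx, oky] + d^2
  }
  sqrt(acc)
}

#' Euclidean distance to the nearest feature cell
#'
#' Cell-center to cell-center Euclidean distance from every cell to the
#' nearest cell where the binary feature raster is 1 (feature cells get 0).
#' An empty feature layer yields the sentinel distance everywhere, with a
#' warning; the default sentinel is the extent diagonal.
#'
#' @param feature a \code{bm_raster} with values 0/1
#' @param sentinel distance (meters) reported when no feature cell exists
#' @return a \code{bm_raster} of distances in meters
#' @export
distance_to <- function(feature, sentinel = NULL) {
  stopifnot(inherits(feature, "bm_raster"))
  if (is.null(sentinel)) sentinel <- sqrt(2) * max(feature$nx, feature$ny) * feature$res
  bm_raster(distance_matrix(feature$values, feature$res, sentinel),
            res = feature$res, xmin = feature$xmin, ymin = feature$ymin)
}

distance_matrix <- function(m, res, sentinel) {
  if (!any(m == 1)) {
    warning("empty feature layer: distance set to sentinel everywhere")
    return(matrix(sentinel, nrow(m), ncol(m)))
  }
  # EBImage::distmap: distance of non-zero pixels to the nearest zero pixel,
  # in cell units; invert the mask so features are the zeros.
  d <- EBImage::distmap(1 - (m == 1), metric = "euclidean")
  as.matrix(d) * res
}

#' Clearcut presence raster for a calendar year
#'
#' A cell counts as clearcut in \code{query_year} when it is covered by a
#' harvest stand whose first-cut year lies within the previous
#' \code{age_max} years (inclusive on both ends: a stand cut exactly
#' \code{age_max} years ago still counts).
#'
#' @param stands data frame with columns xmin, xmax, ymin, ymax, cut_year
#'   (axis-aligned stand rectangles, meters)
#' @param query_year calendar year of interest
#' @param grid list with nx, ny, res, xmin, ymin describing the target grid
#' @param age_max maximum stand age (years) still counting as clearcut
#' @return 0/1 matrix on the grid
#' @export
clearcut_layer <- function(stands, query_year, grid, age_max = 10) {
  m <- matrix(0, grid$nx, grid$ny)
  if (is.null(stands) || nrow(stands) == 0) return(m)
  age <- query_year - stands$cut_year
  act <- stands[age >= 0 & age <= age_max, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    ix0 <- max(1L, floor((act$xmin[i] - grid$xmin) / grid$res) + 1L)
    ix1 <- min(grid$nx, ceiling((act$xmax[i] - grid$xmin) / grid$res))
    iy0 <- max(1L, floor((act$ymin[i] - grid$ymin) / grid$res) + 1L)
    iy1 <- min(grid$ny, ceiling((act$ymax[i] - grid$ymin) / grid$res))
    if (ix0 <= ix1 && iy0 <= iy1) m[ix0:ix1, iy0:iy1] <- 1
  }
  m
}

#' Extract covariates at point locations
#'
#' Nearest-cell values of every model covariate: bog, clearcut (layer chosen
#' by the point's calendar year when harvest stands are available), TRI and
#' the distance-to-feature layers with their log transforms
#' \code{ln(d + 1)}.
#'
#' @param stack a \code{landscape_stack}
#' @param x,y point coordinates (meters)
#' @param year calendar year(s) for the clearcut layer; default: the stack's
#'   reference year
#' @return data.frame, one row per point, with raw and log-distance columns
#' @export
extract_covariates <- function(stack, x, y, year = NULL) {
  ci <- cell_index(stack, x, y, what = "point")
  idx <- cbind(ci$ix, ci$iy)
  if (is.null(year)) year <- stack$config$ref_year
  year <- rep_len(year, length(x))
  cc <- numeric(length(x))
  for (yr in unique(year)) {
    sel <- year == yr
    lay <- if (yr == stack$config$ref_year) stack$layers$clearcut
           else clearcut_layer(stack$stands, yr, stack, age_max = stack$config$clearcut_age_max)
    cc[sel] <- lay[idx[sel, , drop = FALSE]]
  }
  out <- data.frame(
    bog = stack$layers$bog[idx],
    clearcut = cc,
    tri = stack$layers$tri[idx],
    dist_water = stack$layers$dist_water[idx],
    dist_forestry = stack$layers$dist_forestry[idx],
    dist_public = stack$layers$dist_public[idx],
    dist_building = stack$layers$dist_building[idx])
  for (d in c("dist_water", "dist_forestry", "dist_public", "dist_building"))
    out[[paste0("log_", d)]] <- log(out[[d]] + 1)
  out
}

#' Build a standardization table (mean, sd) from a reference sample
#'
#' @param df data frame holding the reference sample
#' @param covariates column names to standardize
#' @return data.frame(covariate, mean, sd)
#' @export
standardize_table <- function(df, covariates) {
  data.frame(covariate = covariates,
             mean = vapply(covariates, function(v) mean(df[[v]]), 0),
             sd = vapply(covariates, function(v) stats::sd(df[[v]]), 0),
             row.names = NULL)
}

#' Apply (or invert) a standardization table
#'
#' Standardizes with \code{(x - mean) / sd}; exactly invertible via
#' \code{invert = TRUE}.
#'
#' @param df data frame with raw (or standardized) covariate columns
#' @param std table from \code{\link{standardize_table}}
#' @param invert if TRUE, map standardized values back to raw
#' @return data frame with the listed columns transformed
#' @export
apply_standardization <- function(df, std, invert = FALSE) {
  for (i in seq_len(nrow(std))) {
    v <- std$covariate[i]
    if (!v %in% names(df)) next
    if (std$sd[i] == 0) stop("zero-sd covariate in standardization table: ", v)
    df[[v]] <- if (invert) df[[v]] * std$sd[i] + std$mean[i]
               else (df[[v]] - std$mean[i]) / std$sd[i]
  }
  df
}

#' Standardize a single value (natural units to model scale) by name
#' @param value numeric value(s) in natural units
#' @param covariate covariate name in \code{std}
#' @param std standardization table (covariate, mean, sd)
#' @return standardized value(s)
#' @export
std_value <- function(value, covariate, std) {
  i <- match(covariate, std$covariate)
  if (is.na(i)) stop("covariate missing from standardization table: ", covariate)
  (value - std$mean[i]) / std$sd[i]
}
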