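#' Configuration for the synthetic landscape generator
#'
#' Defines the spatial structure of a simulated boreal study landscape on a
#' 25-m metric grid: sparse bogs and clearcuts as thresholded smooth random
#' fields, a dense forestry-road network (spanning tree over random seed
#' points), a few long straight public roads, clustered buildings, lakes, and
#' a smooth elevation field. Defaults emulate a managed boreal forest
#' landscape with ~1.3 km/km2 of forestry roads and ~0.18 km/km2 of public
#' roads.
#'
#' @param extent_m landscape width/height in meters (square); must be a
#'   multiple of \code{resolution_m}
#' @param resolution_m cell size in meters
#' @param forestry_road_density target forestry-road density, km/km2
#' @param public_road_density target public-road density, km/km2
#' @param building_cluster_count number of building clusters (villages)
#' @param cluster_sd_m standard deviation of building scatter within a cluster
#' @param buildings_per_cluster mean buildings per cluster
#' @param bog_fraction,clearcut_fraction,water_fraction target area fractions
#' @param dem_smoothness correlation length of the elevation field, meters
#' @param dem_sd standard deviation of elevation, meters
#' @param ref_year calendar year for which the default clearcut layer is built
#' @param clearcut_age_max stands cut within this many years count as clearcut
#' @param seed integer RNG seed; same config + seed gives identical output
#' @return a \code{landscape_config} list
#' @export
landscape_config <- function(extent_m = 20000, resolution_m = 25,
                             forestry_road_density = 1.27,
                             public_road_density = 0.18,
                             building_cluster_count = 12,
                             cluster_sd_m = 150,
                             buildings_per_cluster = 8,
                             bog_fraction = 0.08,
                             clearcut_fraction = 0.07,
                             water_fraction = 0.04,
                             dem_smoothness = 2000,
                             dem_sd = 40,
                             ref_year = 2015,
                             clearcut_age_max = 10,
                             seed = 1L) {
  fr <- c(bog_fraction, clearcut_fraction, water_fraction)
  if (any(fr < 0 | fr > 1)) stop("all area fractions must be in [0, 1]")
  if (forestry_road_density < 0 || public_road_density < 0)
    stop("road densities must be >= 0")
  if (extent_m %% resolution_m != 0)
    stop("extent_m must be divisible by resolution_m")
  structure(as.list(environment()), class = "landscape_config")
}

# Smooth Gaussian random field via FFT convolution of white noise with a
# Gaussian kernel; returned standardized to mean 0, sd 1.
grf_field <- function(nx, ny, corr_len_cells) {
  noise <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (corr_len_cells <= 0) return(noise)
  dx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  dy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  d2 <- outer(dx^2, dy^2, "+")
  kern <- exp(-d2 / (2 * corr_len_cells^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / (nx * ny)
  (sm - mean(sm)) / stats::sd(sm)
}

# Threshold a field so that `fraction` of cells are 1 (largest values).
threshold_fraction <- function(field, fraction) {
  if (fraction <= 0) return(matrix(0, nrow(field), ncol(field)))
  thr <- stats::quantile(field, 1 - fraction, names = FALSE)
  (field >= thr) * 1
}

# Rasterize a polyline segment (x0,y0)-(x1,y1) onto a 0/1 matrix by dense
# sampling at half-cell spacing.
rasterize_segment <- function(m, res, x0, y0, x1, y1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / (res / 2)))
  tt <- seq(0, 1, length.out = n)
  ix <- floor((x0 + tt * (x1 - x0)) / res) + 1L
  iy <- floor((y0 + tt * (y1 - y0)) / res) + 1L
  keep <- ix >= 1 & ix <= nrow(m) & iy >= 1 & iy <= ncol(m)
  m[cbind(ix[keep], iy[keep])] <- 1
  m
}

# Minimum spanning tree (Prim) over points; returns an edge index matrix.
mst_edges <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), 0, 2))
  in_tree <- logical(n); in_tree[1] <- TRUE
  best_d <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  best_from <- rep(1L, n)
  edges <- matrix(integer(0), 0, 2)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges <- rbind(edges, c(best_from[j], j))
    in_tree[j] <- TRUE
    d_new <- (pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2
    upd <- !in_tree & d_new < best_d
    best_d[upd] <- d_new[upd]; best_from[upd] <- j
  }
  edges
}

# Forestry roads: MST over random seed points, topped up with extra
# short edges until the target total length is reached.
gen_forestry_roads <- function(cfg) {
  nx <- cfg$extent_m / cfg$resolution_m
  m <- matrix(0, nx, nx)
  area_km2 <- (cfg$extent_m / 1000)^2
  target_m <- cfg$forestry_road_density * area_km2 * 1000
  if (target_m <= 0) return(list(raster = m, length_m = 0))
  # MST total length over n uniform points in area A is ~ 0.68 * sqrt(n * A)
  n_pts <- max(3L, ceiling((target_m / (0.68 * sqrt(cfg$extent_m^2)))^2))
  pts <- cbind(stats::runif(n_pts, 0, cfg$extent_m), stats::runif(n_pts, 0, cfg$extent_m))
  ed <- mst_edges(pts)
  seg_len <- sqrt(rowSums((pts[ed[, 1], , drop = FALSE] - pts[ed[, 2], , drop = FALSE])^2))
  ord <- sample.int(nrow(ed))
  total <- 0
  for (e in ord) {
    if (total >= target_m) break
    m <- rasterize_segment(m, cfg$resolution_m, pts[ed[e, 1], 1], pts[ed[e, 1], 2],
                           pts[ed[e, 2], 1], pts[ed[e, 2], 2])
    total <- total + seg_len[e]
  }
  # top up with short random spur edges if the MST fell short
  while (total < target_m) {
    i <- sample.int(n_pts, 1)
    ang <- stats::runif(1, 0, 2 * pi); len <- stats::runif(1, 500, 1500)
    x1 <- min(max(pts[i, 1] + len * cos(ang), 0), cfg$extent_m)
    y1 <- min(max(pts[i, 2] + len * sin(ang), 0), cfg$extent_m)
    m <- rasterize_segment(m, cfg$resolution_m, pts[i, 1], pts[i, 2], x1, y1)
    total <- total + sqrt((x1 - pts[i, 1])^2 + (y1 - pts[i, 2])^2)
  }
  list(raster = m, length_m = total)
}

# Public roads: few long straight lines through random points.
gen_public_roads <- function(cfg) {
  nx <- cfg$extent_m / cfg$resolution_m
  m <- matrix(0, nx, nx)
  area_km2 <- (cfg$extent_m / 1000)^2
  target_m <- cfg$public_road_density * area_km2 * 1000
  total <- 0
  while (total < target_m) {
    px <- stats::runif(1, 0, cfg$extent_m); py <- stats::runif(1, 0, cfg$extent_m)
    ang <- stats::runif(1, 0, pi)
    big <- 2 * cfg$extent_m
    x0 <- px - big * cos(ang); y0 <- py - big * sin(ang)
    x1 <- px + big * cos(ang); y1 <- py + big * sin(ang)
    cl <- clip_segment(x0, y0, x1, y1, 0, cfg$extent_m)
    if (is.null(cl)) next
    m <- rasterize_segment(m, cfg$resolution_m, cl[1], cl[2], cl[3], cl[4])
    total <- total + sqrt((cl[3] - cl[1])^2 + (cl[4] - cl[2])^2)
  }
  list(raster = m, length_m = total)
}

# Liang-Barsky clip of a segment to the square [lo, hi]^2.
clip_segment <- function(x0, y0, x1, y1, lo, hi) {
  dx <- x1 - x0; dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - lo, hi - x0, y0 - lo, hi - y0)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) { if (q[i] < 0) return(NULL) } else {
      r <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(NULL)
  c(x0 + t0 * dx, y0 + t0 * dy, x0 + t1 * dx, y0 + t1 * dy)
}

# Rectangular harvest stands covering ~ the target fraction, with first-cut years.
gen_stands <- function(cfg) {
  target_area <- cfg$clearcut_fraction * cfg$extent_m^2
  stands <- list(); tot <- 0
  while (tot < target_area) {
    w <- stats::runif(1, 200, 800); h <- stats::runif(1, 200, 800)
    x0 <- stats::runif(1, 0, cfg$extent_m - w); y0 <- stats::runif(1, 0, cfg$extent_m - h)
    yr <- sample(seq(cfg$ref_year - cfg$clearcut_age_max - 4, cfg$ref_year), 1)
    stands[[length(stands) + 1]] <- c(xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h, cut_year = yr)
    tot <- tot + w * h
  }
  as.data.frame(do.call(rbind, stands))
}

#' Generate a synthetic landscape covariate stack
#'
#' Builds aligned rasters of bogs, clearcuts (per year), water, elevation and
#' terrain ruggedness, forestry roads, public roads and buildings, plus
#' Euclidean distance-to-feature layers and their log transforms, on a square
#' metric grid. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{landscape_config}}
#' @return a \code{landscape_stack}: list of layer matrices, grid metadata,
#'   harvest-stand table, and a landscape-wide standardization table
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  cfg <- config
  nx <- as.integer(cfg$extent_m / cfg$resolution_m)
  res <- cfg$resolution_m
  with_seed(cfg$seed, {
    corr_cells <- 8  # ~200 m patch scale for habitat fields at 25 m
    bog <- threshold_fraction(grf_field(nx, nx, corr_cells), cfg$bog_fraction)
    water <- threshold_fraction(grf_field(nx, nx, corr_cells * 2), cfg$water_fraction)
    bog[water == 1] <- 0
    dem <- grf_field(nx, nx, cfg$dem_smoothness / res) * cfg$dem_sd + 300
    stands <- gen_stands(cfg)
    fr <- gen_forestry_roads(cfg)
    pr <- gen_public_roads(cfg)
    # buildings clustered around village centers
    bld <- matrix(0, nx, nx)
    if (cfg$building_cluster_count > 0) {
      cx <- stats::runif(cfg$building_cluster_count, 0, cfg$extent_m)
      cy <- stats::runif(cfg$building_cluster_count, 0, cfg$extent_m)
      for (i in seq_len(cfg$building_cluster_count)) {
        nb <- max(1L, stats::rpois(1, cfg$buildings_per_cluster))
        bx <- pmin(pmax(stats::rnorm(nb, cx[i], cfg$cluster_sd_m), 0), cfg$extent_m - 1)
        by <- pmin(pmax(stats::rnorm(nb, cy[i], cfg$cluster_sd_m), 0), cfg$extent_m - 1)
        bld[cbind(floor(bx / res) + 1L, floor(by / res) + 1L)] <- 1
      }
    }
    grid <- list(nx = nx, ny = nx, res = res, xmin = 0, ymin = 0)
    clearcut <- clearcut_layer(stands, cfg$ref_year, grid, age_max = cfg$clearcut_age_max)
    tri <- compute_tri_matrix(dem)
    sentinel <- sqrt(2) * cfg$extent_m
    layers <- list(
      bog = bog, clearcut = clearcut, water = water, dem = dem, tri = tri,
      forestry_road = fr$raster, public_road = pr$raster, building = bld,
      dist_water = distance_matrix(water, res, sentinel),
      dist_forestry = distance_matrix(fr$raster, res, sentinel),
      dist_public = distance_matrix(pr$raster, res, sentinel),
      dist_building = distance_matrix(bld, res, sentinel))
    for (d in c("dist_water", "dist_forestry", "dist_public", "dist_building"))
      layers[[paste0("log_", d)]] <- log(layers[[d]] + 1)
    stack <- structure(c(grid, list(
      layers = layers, stands = stands, config = cfg,
      road_length_m = c(forestry = fr$length_m, public = pr$length_m))),
      class = "landscape_stack")
    stack$std <- landscape_std_table(stack)
    stack
  })
}

# Landscape-wide standardization table over all cells, for the model covariates.
landscape_std_table <- function(stack) {
  covs <- c("bog", "clearcut", "tri", "log_dist_water", "log_dist_forestry",
            "log_dist_public", "log_dist_building")
  data.frame(covariate = covs,
             mean = vapply(covs, function(v) mean(stack$layers[[v]]), 0),
             sd = vapply(covs, function(v) stats::sd(stack$layers[[v]]), 0),
             row.names = NULL)
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d cells at %g m (%g x %g km)\n",
              x$nx, x$ny, x$res, x$nx * x$res / 1000, x$ny * x$res / 1000))
  cat(sprintf("  bog %.3f, clearcut %.3f, water %.3f of area; roads %.2f / %.2f km/km2 (forestry/public)\n",
              mean(x$layers$bog), mean(x$layers$clearcut), mean(x$layers$water),
              x$road_length_m["forestry"] / 1000 / (x$nx * x$res / 1000)^2,
              x$road_length_m["public"] / 1000 / (x$nx * x$res / 1000)^2))
  invisible(x)
}

# Helper to view a named layer as a bm_raster.
#' Extract one layer of a landscape stack as a raster object
#' @param stack a \code{landscape_stack}
#' @param name layer name, e.g. "bog" or "dist_forestry"
#' @return a \code{bm_raster}
#' @export
stack_layer <- function(stack, name) {
  if (is.null(stack$layers[[name]])) stop("no such layer: ", name)
  bm_raster(stack$layers[[name]], res = stack$res, xmin = stack$xmin, ymin = stack$ymin)
}

#' Write all landscape layers as ESRI ASCII grids plus a JSON sidecar
#' @param stack a \code{landscape_stack}
#' @param dir output directory (created if needed)
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_asc(stack_layer(stack, nm), file.path(dir, paste0(nm, ".asc")))
  meta <- list(resolution_m = stack$res, nx = stack$nx, ny = stack$ny,
               config = unclass(stack$config), std = stack$std)
  jsonlite::write_json(meta, file.path(dir, "landscape.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
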