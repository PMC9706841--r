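#' Landscape-scale availability region (buffered minimum convex polygon)
#'
#' The 100% minimum convex polygon of all fixes from all bear-years,
#' buffered by the radius of a circular mean male home range (18 km by
#' default).
#'
#' @param tracks a track data.frame or list of track data.frames
#' @param buffer_m buffer radius in meters
#' @return an \code{availability_region}: hull vertex matrix (counter-
#'   clockwise), buffer, and closed-form area of the buffered hull
#' @export
build_availability <- function(tracks, buffer_m = 18000) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  x <- unlist(lapply(tracks, `[[`, "x"))
  y <- unlist(lapply(tracks, `[[`, "y"))
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) stop("need at least 3 distinct fixes for a convex polygon")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  # chull returns clockwise order; reverse to counter-clockwise
  if (polygon_area_signed(hull) < 0) hull <- hull[nrow(hull):1, , drop = FALSE]
  area0 <- polygon_area_signed(hull)
  if (area0 <= 0) stop("degenerate (collinear) fixes: hull has zero area")
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), , drop = FALSE])^2)))
  structure(list(hull = hull, buffer_m = buffer_m,
                 area_m2 = area0 + per * buffer_m + pi * buffer_m^2),
            class = "availability_region")
}

#' @export
print.availability_region <- function(x, ...) {
  cat(sprintf("<availability_region> MCP with %d vertices + %.1f km buffer; area %.1f km2\n",
              nrow(x$hull), x$buffer_m / 1000, x$area_m2 / 1e6))
  invisible(x)
}

polygon_area_signed <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Distance from points to a convex polygon (0 inside), vectorized over points.
dist_to_hull <- function(hull, px, py) {
  n <- nrow(hull)
  j <- c(2:n, 1)
  inside <- rep(TRUE, length(px))
  mind <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    ax <- hull[e, 1]; ay <- hull[e, 2]
    bx <- hull[j[e], 1]; by <- hull[j[e], 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    inside <- inside & cross >= 0  # CCW orientation: inside is left of edges
    # point-segment distance
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2), 0), 1)
    mind <- pmin(mind, sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2))
  }
  ifelse(inside, 0, mind)
}

#' Membership test for the buffered availability region
#' @param region an \code{availability_region}
#' @param x,y point coordinates
#' @return logical vector
#' @export
region_contains <- function(region, x, y) {
  dist_to_hull(region$hull, x, y) <= region$buffer_m
}

#' Sample available locations within the availability region
#'
#' Uniform points inside the buffered MCP, intersected with the raster
#' extent and excluding water cells when a landscape is supplied; a 20:1
#' available-to-used ratio by default. Deterministic under \code{seed}.
#'
#' @param region an \code{availability_region}
#' @param n_used number of used fixes for this bear-year
#' @param ratio available-to-used ratio
#' @param seed integer seed
#' @param stack optional \code{landscape_stack} for extent/water masking
#' @return data.frame with columns x, y (\code{ratio * n_used} rows)
#' @export
sample_available <- function(region, n_used, ratio = 20, seed = 1L, stack = NULL) {
  n_target <- ratio * n_used
  bb <- apply(region$hull, 2, range)
  bb[1, ] <- bb[1, ] - region$buffer_m
  bb[2, ] <- bb[2, ] + region$buffer_m
  if (!is.null(stack)) {
    ext <- raster_extent(stack_layer(stack, "water"))
    bb[1, 1] <- max(bb[1, 1], ext["xmin"]); bb[2, 1] <- min(bb[2, 1], ext["xmax"] - 1e-9)
    bb[1, 2] <- max(bb[1, 2], ext["ymin"]); bb[2, 2] <- min(bb[2, 2], ext["ymax"] - 1e-9)
    if (bb[1, 1] >= bb[2, 1] || bb[1, 2] >= bb[2, 2])
      stop("availability region lies outside the raster extent")
  }
  with_seed(seed, {
    out_x <- numeric(0); out_y <- numeric(0)
    guard <- 0
    while (length(out_x) < n_target) {
      m <- max(1000L, 2L * (n_target - length(out_x)))
      cx <- stats::runif(m, bb[1, 1], bb[2, 1])
      cy <- stats::runif(m, bb[1, 2], bb[2, 2])
      ok <- region_contains(region, cx, cy)
      if (!is.null(stack))
        ok <- ok & raster_lookup(stack_layer(stack, "water"), cx, cy) != 1
      out_x <- c(out_x, cx[ok]); out_y <- c(out_y, cy[ok])
      guard <- guard + 1
      if (guard > 1000) stop("rejection sampling failed: acceptance region too small")
    }
    data.frame(x = out_x[seq_len(n_target)], y = out_y[seq_len(n_target)])
  })
}

#' Fit a landscape-scale resource selection function
#'
#' Exponential RSF fitted as a used-versus-available logistic regression
#' (1 = used, 0 = available) by \code{stats::glm}. The input data must carry
#' the (standardized) covariate columns named in \code{terms}.
#'
#' @param data data.frame with a 0/1 \code{case} column and covariates
#' @param terms model terms (see \code{\link{candidate_models}})
#' @param model_name label stored with the fit
#' @param bear_year_id identifier stored with the fit
#' @return object of class \code{rsf_fit}
#' @export
fit_rsf <- function(data, terms, model_name = "model", bear_year_id = NA_character_) {
  X <- build_design(data, terms)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient RSF design; offending covariate(s): ",
         paste(drop, collapse = ", "))
  }
  df <- data.frame(case = data$case, X, check.names = FALSE)
  fit <- stats::glm(case ~ ., family = stats::binomial(), data = df)
  if (!fit$converged) stop("RSF logistic regression did not converge")
  sm <- summary(fit)
  structure(list(
    bear_year_id = bear_year_id, model_name = model_name, terms = terms,
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    vcov = stats::vcov(fit),
    log_likelihood = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n_used = sum(data$case == 1), n_available = sum(data$case == 0),
    glm = fit), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %s / %s: %d used, %d available, AIC %.2f\n",
              x$bear_year_id, x$model_name, x$n_used, x$n_available, x$aic))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.rsf_fit <- function(object, ...) object$coefficients

#' @export
vcov.rsf_fit <- function(object, ...) object$vcov

#' @export
logLik.rsf_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients), class = "logLik")
}

#' @export
AIC.rsf_fit <- function(object, ..., k = 2) {
  k * length(object$coefficients) - 2 * object$log_likelihood
}
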