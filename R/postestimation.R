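#' Adjust the tentative gamma kernel with fitted movement coefficients
#'
#' The conditional-logit coefficients on SL, lnSL and the lnSL x start-
#' covariate interactions act as modifiers of the tentative gamma:
#' \deqn{shape' = shape + \beta_{lnSL} + \sum_j \beta_{lnSL:x_j} x_j}
#' \deqn{scale' = 1 / (1/scale - \beta_{SL})}
#' with the start covariates \eqn{x_j} on the model (standardized) scale.
#' The expected movement rate is \code{shape' * scale'} meters per hour.
#'
#' @param kernel tentative \code{\link{gamma_kernel}}
#' @param coefs named coefficient vector (from an \code{issa_clogit});
#'   \code{"sl"}, \code{"log_sl"} and \code{"log_sl:<cov>_start"} entries are
#'   used, absent ones count as zero
#' @param start_covariates named numeric vector of standardized start-
#'   covariate values for the interaction terms
#' @return adjusted \code{gamma_kernel}
#' @export
adjust_gamma <- function(kernel, coefs, start_covariates = numeric(0)) {
  stopifnot(inherits(kernel, "gamma_kernel"))
  b_sl <- if ("sl" %in% names(coefs)) coefs[["sl"]] else 0
  b_lsl <- if ("log_sl" %in% names(coefs)) coefs[["log_sl"]] else 0
  inter <- coefs[grepl("^log_sl:", names(coefs))]
  add <- 0
  for (nm in names(inter)) {
    cov <- sub("^log_sl:", "", nm)
    if (!cov %in% names(start_covariates))
      stop("start covariate value missing for interaction term: ", nm)
    add <- add + inter[[nm]] * start_covariates[[cov]]
  }
  shape_adj <- kernel$shape + b_lsl + add
  rate_adj <- 1 / kernel$scale - b_sl
  if (shape_adj <= 0)
    stop(sprintf("non-positive adjusted shape (%.4f) at start covariates [%s]",
                 shape_adj, paste(sprintf("%s = %.3f", names(start_covariates),
                                          start_covariates), collapse = ", ")))
  if (rate_adj <= 0)
    stop(sprintf("non-positive adjusted rate (%.6f)", rate_adj))
  gamma_kernel(shape = shape_adj, scale = 1 / rate_adj)
}

#' Movement-rate curve over a focal start covariate
#'
#' For each bear-year model, the expected movement rate (adjusted shape x
#' adjusted scale, meters/hour) is evaluated on a grid of the focal
#' distance covariate in natural units, holding the other interacting
#' covariates at their mean observed used-step start values; the population
#' curve is the unweighted mean across bear-years. Bear-years whose adjusted
#' parameters leave the valid range are excluded with a warning.
#'
#' @param models list of per-bear-year model bundles, each a list with
#'   \code{coefs} (named vector), \code{kernel} (tentative
#'   \code{gamma_kernel}), \code{std} (standardization table) and
#'   \code{start_means} (named natural-unit means of the used-step start
#'   covariates, e.g. \code{c(dist_forestry = 250, ...)})
#' @param focal focal covariate base name, e.g. \code{"log_dist_forestry"}
#'   (grid below is in meters before the log transform)
#' @param grid_m grid of natural distances in meters
#' @return data.frame: distance_m, rate (m/h), level ("population" plus one
#'   row set per bear-year index)
#' @export
rate_curve <- function(models, focal, grid_m = seq(0, 500, by = 25)) {
  focal_key <- if (grepl("_start$", focal)) focal else paste0(focal, "_start")
  raw_focal <- sub("_start$", "", focal_key)
  per_by <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    inter_covs <- sub("^log_sl:", "", names(m$coefs)[grepl("^log_sl:", names(m$coefs))])
    if (!focal_key %in% inter_covs)
      stop("focal covariate not among fitted interactions: ", focal)
    start_std <- vapply(inter_covs, function(cov) {
      raw_name <- sub("_start$", "", cov)
      nat <- m$start_means[[raw_name]]
      if (is.null(nat)) stop("start mean missing for covariate: ", raw_name)
      std_value(nat, raw_name, m$std)
    }, 0)
    rates <- vapply(grid_m, function(d) {
      sv <- start_std
      sv[[focal_key]] <- std_value(log(d + 1), raw_focal, m$std)
      k <- tryCatch(adjust_gamma(m$kernel, m$coefs, sv), error = function(e) NULL)
      if (is.null(k)) NA_real_ else k$shape * k$scale
    }, 0)
    per_by[[i]] <- rates
  }
  ok <- !vapply(per_by, function(r) any(is.na(r)), TRUE)
  if (any(!ok)) warning(sum(!ok), " bear-year(s) excluded from the rate curve ",
                        "(adjusted gamma out of range)")
  rows <- do.call(rbind, lapply(which(ok), function(i)
    data.frame(distance_m = grid_m, rate = per_by[[i]], level = paste0("bear_year_", i))))
  pop <- data.frame(distance_m = grid_m,
                    rate = colMeans(do.call(rbind, per_by[ok])),
                    level = "population")
  rbind(pop, rows)
}

#' Log relative selection strength between two locations
#'
#' \deqn{ln RSS(x_1, x_2) = \sum_j \beta_j (h_j(x_1) - h_j(x_2))}
#' for covariate vectors on the model scale. RSS(x, x) = 1 and
#' RSS(x1, x2) * RSS(x2, x1) = 1 by construction.
#'
#' @param beta named coefficient vector (population-averaged estimates)
#' @param h1,h2 named covariate vectors on the model scale; names must cover
#'   \code{names(beta)}
#' @return list with \code{log_rss} and \code{rss}
#' @export
rss <- function(beta, h1, h2) {
  miss <- setdiff(names(beta), union(names(h1), names(h2)))
  if (length(miss)) stop("covariate(s) absent from locations: ",
                         paste(miss, collapse = ", "))
  d <- vapply(names(beta), function(v) (h1[[v]] %||% 0) - (h2[[v]] %||% 0), 0)
  lr <- sum(beta * d)
  list(log_rss = lr, rss = exp(lr))
}

#' RSS curve for moving one mean step length closer to a feature
#'
#' For a distance-to-feature covariate, compares a step ending one mean step
#' length closer to the feature (floored at distance zero) with a step
#' ending at the same distance, across a grid of current distances; the log
#' then standardize transform is applied to both locations.
#'
#' @param beta population-averaged coefficient on the (standardized log)
#'   distance covariate
#' @param covariate covariate base name, e.g. \code{"log_dist_forestry"}
#' @param std standardization table
#' @param mean_sl mean step length, meters
#' @param grid_m grid of current distances, meters
#' @return data.frame: distance_m, log_rss, rss
#' @export
rss_distance_curve <- function(beta, covariate, std, mean_sl,
                               grid_m = seq(0, 500, by = 25)) {
  h <- function(d) std_value(log(d + 1), covariate, std)
  out <- data.frame(distance_m = grid_m)
  out$log_rss <- vapply(grid_m, function(d)
    beta * (h(max(d - mean_sl, 0)) - h(d)), 0)
  out$rss <- exp(out$log_rss)
  out
}

#' RSS of a habitat value relative to the covariate mean
#'
#' For non-distance covariates, the relative selection strength of a given
#' (natural-unit) covariate value over the reference value, which defaults
#' to the standardization mean.
#'
#' @param beta population-averaged coefficient (standardized scale)
#' @param covariate covariate name in \code{std}
#' @param std standardization table
#' @param value natural-unit covariate value(s) of interest
#' @param reference natural-unit reference value; default: the mean in
#'   \code{std} (standardized 0)
#' @return data.frame: value, log_rss, rss
#' @export
rss_habitat <- function(beta, covariate, std, value, reference = NULL) {
  i <- match(covariate, std$covariate)
  if (is.na(i)) stop("covariate missing from standardization table: ", covariate)
  ref_z <- if (is.null(reference)) 0 else std_value(reference, covariate, std)
  z <- (value - std$mean[i]) / std$sd[i]
  data.frame(value = value, log_rss = beta * (z - ref_z),
             rss = exp(beta * (z - ref_z)))
}
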