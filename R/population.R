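#' Within-bear-year AIC model selection summary
#'
#' For every bear-year, the AIC difference of each candidate model from that
#' bear-year's best model; summarized per model as the mean delta-AIC across
#' bear-years and the minimum-AIC tally (the number of bear-years for which
#' the model is best). The life-stage best model is the one with the lowest
#' mean delta-AIC; note its mean delta-AIC can exceed 0, since no single
#' structure need win in every bear-year.
#'
#' @param fits data.frame with columns \code{bear_year_id},
#'   \code{model_name}, \code{aic}
#' @return a \code{selection_summary} data.frame: model_name, mean_delta_aic,
#'   n_best, prop_best, sorted by mean delta-AIC, with attributes
#'   \code{best_model} and \code{n_bear_years}
#' @export
summarize_selection <- function(fits) {
  need <- c("bear_year_id", "model_name", "aic")
  stopifnot(all(need %in% names(fits)))
  models <- unique(fits$model_name)
  complete <- tapply(fits$model_name, fits$bear_year_id,
                     function(m) all(models %in% m))
  if (any(!complete)) {
    warning(sum(!complete), " bear-year(s) without the full candidate set excluded")
    fits <- fits[fits$bear_year_id %in% names(complete)[complete], , drop = FALSE]
  }
  by_id <- split(fits, fits$bear_year_id)
  n_by <- length(by_id)
  delta <- lapply(by_id, function(d) {
    d$delta_aic <- d$aic - min(d$aic)
    d$is_best <- seq_len(nrow(d)) == which.min(d$aic)
    d
  })
  all_d <- do.call(rbind, delta)
  out <- data.frame(
    model_name = models,
    mean_delta_aic = vapply(models, function(m)
      mean(all_d$delta_aic[all_d$model_name == m]), 0),
    n_best = vapply(models, function(m)
      sum(all_d$is_best[all_d$model_name == m]), 0),
    row.names = NULL)
  out$prop_best <- out$n_best / n_by
  out <- out[order(out$mean_delta_aic), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, best_model = out$model_name[1], n_bear_years = n_by,
            class = c("selection_summary", "data.frame"))
}

#' Inverse-variance-weighted population estimate for one coefficient
#'
#' Second-stage fixed-effects meta-regression: bear-year coefficients are
#' regressed on their centered mean availability with weights equal to the
#' inverse estimated coefficient variances. The population estimate is the
#' intercept (the mean coefficient at mean availability); the availability
#' slope is retained as a functional-response check. With no (or constant)
#' availability the model reduces to the inverse-variance weighted mean.
#'
#' @param estimates per-bear-year coefficient values
#' @param variances per-bear-year estimated variances (> 0)
#' @param availability per-bear-year mean availability of the covariate, or
#'   NULL for a plain weighted mean
#' @param ci_mult multiplier for the 95% CI half-width (1.96: normal)
#' @return object of class \code{ivw_fit}: estimate, se, ci_low, ci_high,
#'   availability_slope (+ se), classification helper fields, n
#' @export
ivw_estimate <- function(estimates, variances, availability = NULL, ci_mult = 1.96) {
  stopifnot(length(estimates) >= 3, length(variances) == length(estimates),
            all(variances > 0))
  w <- 1 / variances
  use_avail <- !is.null(availability) && stats::sd(availability) > 0
  if (use_avail) {
    a_c <- availability - mean(availability)
    fit <- stats::lm(estimates ~ a_c, weights = w)
    est <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    slope <- unname(stats::coef(fit)[2])
    slope_se <- sqrt(stats::vcov(fit)[2, 2])
  } else {
    if (!is.null(availability))
      message("constant availability: falling back to inverse-variance weighted mean")
    est <- sum(w * estimates) / sum(w)
    # weighted-mean SE from the weighted residual variance (lm convention)
    n <- length(estimates)
    s2 <- sum(w * (estimates - est)^2) / (n - 1)
    se <- sqrt(s2 / sum(w))
    slope <- NA_real_; slope_se <- NA_real_
  }
  structure(list(estimate = est, se = se,
                 ci_low = est - ci_mult * se, ci_high = est + ci_mult * se,
                 availability_slope = slope, availability_slope_se = slope_se,
                 n = length(estimates), ci_mult = ci_mult), class = "ivw_fit")
}

#' @export
print.ivw_fit <- function(x, ...) {
  cat(sprintf("<ivw_fit> estimate %.4f [%.4f, %.4f] (n = %d)\n",
              x$estimate, x$ci_low, x$ci_high, x$n))
  if (is.finite(x$availability_slope))
    cat(sprintf("  availability slope %.4f (se %.4f)\n",
                x$availability_slope, x$availability_slope_se))
  invisible(x)
}

#' @export
coef.ivw_fit <- function(object, ...) c(estimate = object$estimate,
                                        availability_slope = object$availability_slope)

#' @export
confint.ivw_fit <- function(object, ...) c(object$ci_low, object$ci_high)

#' Classify a population-level effect from its 95% CI
#'
#' "Indifferent" when the CI covers zero; otherwise the label depends on the
#' covariate kind: for habitat presence/value covariates a positive estimate
#' means selection; for distance-to-feature covariates a positive estimate
#' (selecting larger distances) means avoidance of the feature; for lnSL x
#' distance movement interactions a negative estimate means faster movement
#' closer to the feature.
#'
#' @param fit an \code{ivw_fit}
#' @param kind "habitat", "distance", or "movement_distance"
#' @return character label
#' @export
classify_effect <- function(fit, kind = c("habitat", "distance", "movement_distance")) {
  kind <- match.arg(kind)
  if (fit$ci_low <= 0 && fit$ci_high >= 0) return("indifferent")
  pos <- fit$estimate > 0
  switch(kind,
         habitat = if (pos) "selected" else "avoided",
         distance = if (pos) "avoided" else "selected",
         movement_distance = if (pos) "slower" else "faster")
}

#' Proportion of bear-years whose coefficient matches the population sign
#'
#' A coefficient of exactly zero counts as not matching; a zero population
#' estimate makes the proportion undefined (NA).
#'
#' @param coefs per-bear-year coefficients
#' @param estimate population-level estimate
#' @return fraction in [0, 1], or NA
#' @export
direction_proportion <- function(coefs, estimate) {
  if (estimate == 0) return(NA_real_)
  mean(sign(coefs) == sign(estimate))
}

# Covariate kind lookup for classification of the standard model terms.
term_kind <- function(term) {
  if (grepl("^log_sl:", term)) return("movement_distance")
  if (grepl("log_dist", term)) return("distance")
  "habitat"
}

#' Population estimates table for a candidate model across bear-years
#'
#' Runs the IVW second stage for every coefficient of \code{model_name}
#' across bear-year fits and emits one row per coefficient: estimate, 95% CI,
#' classification, and the proportion of bear-years sharing the population
#' sign.
#'
#' @param fit_list list of per-bear-year fits (\code{issa_clogit} or
#'   \code{rsf_fit}) for one model structure
#' @param availability optional data.frame of per-bear-year mean
#'   availabilities, columns named by covariate (rows aligned to
#'   \code{fit_list})
#' @param terms coefficients to summarize; default: all shared coefficients
#'   except an intercept
#' @return a Table-4-shaped data.frame: coefficient, estimate, ci_low,
#'   ci_high, prop_direction, classification, n
#' @export
population_estimates <- function(fit_list, availability = NULL, terms = NULL) {
  stopifnot(length(fit_list) >= 3)
  cf <- lapply(fit_list, stats::coef)
  vc <- lapply(fit_list, function(f) diag(stats::vcov(f)))
  if (is.null(terms)) terms <- setdiff(names(cf[[1]]), "(Intercept)")
  rows <- lapply(terms, function(tm) {
    est_i <- vapply(cf, `[[`, 0, tm)
    var_i <- vapply(vc, `[[`, 0, tm)
    av <- NULL
    if (!is.null(availability)) {
      base <- sub("^log_sl:", "", tm)
      base <- sub("_(end|start)$", "", base)
      if (base %in% names(availability)) av <- availability[[base]]
    }
    fit <- ivw_estimate(est_i, var_i, availability = av)
    data.frame(coefficient = tm, estimate = fit$estimate,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               prop_direction = direction_proportion(est_i, fit$estimate),
               classification = classify_effect(fit, term_kind(tm)),
               availability_slope = fit$availability_slope,
               n = fit$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
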