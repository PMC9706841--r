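#' Build used steps from a cleaned track
#'
#' Steps join consecutive non-bed fixes exactly one hour apart. Turning
#' angles require a contiguous previous step, so strata break at gaps and at
#' removed bed sites; steps without a turning angle never enter strata.
#'
#' @param track cleaned track with a logical \code{bed_site} column (fixes
#'   flagged TRUE are dropped before step construction); a missing column
#'   means no beds
#' @return data.frame of used steps (see \code{\link{movement_steps}})
#' @export
build_steps <- function(track) {
  if (!is.null(track$bed_site)) track <- track[!track$bed_site, , drop = FALSE]
  movement_steps(track)
}

#' Tentative gamma step-length kernel (pooled MLE)
#'
#' Maximum-likelihood gamma fit to the used step lengths of all bear-years,
#' both life stages combined, used to sample available step lengths.
#'
#' @param sl positive step lengths (meters), pooled
#' @return object of class \code{gamma_kernel} with \code{shape} and
#'   \code{scale} (meters)
#' @export
fit_tentative_gamma <- function(sl) {
  sl <- sl[is.finite(sl)]
  if (length(sl) < 30) stop("need at least 30 step lengths for the tentative gamma")
  if (any(sl <= 0)) sl[sl <= 0] <- min(sl[sl > 0]) / 2
  if (stats::sd(sl) == 0) stop("degenerate (constant) step lengths")
  est <- suppressWarnings(MASS::fitdistr(sl, "gamma"))$estimate
  gamma_kernel(shape = unname(est["shape"]), scale = 1 / unname(est["rate"]))
}

#' Construct a gamma step-length kernel
#' @param shape,scale gamma parameters (scale in meters), both positive
#' @return a \code{gamma_kernel}
#' @export
gamma_kernel <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale), class = "gamma_kernel")
}

#' @export
print.gamma_kernel <- function(x, ...) {
  cat(sprintf("<gamma_kernel> shape %.4f, scale %.2f m (mean %.1f m/h)\n",
              x$shape, x$scale, x$shape * x$scale))
  invisible(x)
}

#' Generate matched available steps (20:1)
#'
#' For every used step with a defined turning angle, draws \code{ratio}
#' available steps from the same start point: lengths from the tentative
#' gamma kernel and turning angles uniform on (-pi, pi] around the previous
#' heading. Endpoints outside the landscape are redrawn up to
#' \code{max_retry} times.
#'
#' @param steps used steps from \code{\link{build_steps}}
#' @param kernel a \code{gamma_kernel}
#' @param ratio available steps per used step
#' @param seed integer seed
#' @param stack optional \code{landscape_stack}; when given, available
#'   endpoints are kept inside its extent
#' @param max_retry redraw attempts per available step
#' @return a \code{step_set} data.frame: stratum, case (1 used/0 available),
#'   t, x0, y0, x1, y1, sl, log_sl, ta, cos_ta
#' @export
generate_available_steps <- function(steps, kernel, ratio = 20, seed = 1L,
                                     stack = NULL, max_retry = 100L) {
  stopifnot(inherits(kernel, "gamma_kernel"))
  use <- steps[!is.na(steps$ta), , drop = FALSE]
  if (nrow(use) == 0) stop("no steps with defined turning angles")
  prev_heading <- use$heading - use$ta
  n <- nrow(use)
  with_seed(seed, {
    m <- n * ratio
    idx <- rep(seq_len(n), each = ratio)
    sl <- stats::rgamma(m, shape = kernel$shape, scale = kernel$scale)
    ta <- stats::runif(m, -pi, pi)
    ang <- prev_heading[idx] + ta
    ex <- use$x0[idx] + sl * cos(ang)
    ey <- use$y0[idx] + sl * sin(ang)
    if (!is.null(stack)) {
      bad <- which(!raster_inside(stack, ex, ey))
      tries <- 0
      while (length(bad)) {
        tries <- tries + 1
        if (tries > max_retry)
          stop("could not place available endpoints inside the landscape (",
               length(bad), " left after ", max_retry, " redraws)")
        sl[bad] <- stats::rgamma(length(bad), shape = kernel$shape, scale = kernel$scale)
        ta[bad] <- stats::runif(length(bad), -pi, pi)
        ang[bad] <- prev_heading[idx[bad]] + ta[bad]
        ex[bad] <- use$x0[idx[bad]] + sl[bad] * cos(ang[bad])
        ey[bad] <- use$y0[idx[bad]] + sl[bad] * sin(ang[bad])
        bad <- bad[!raster_inside(stack, ex[bad], ey[bad])]
      }
    }
    used_rows <- data.frame(stratum = seq_len(n), case = 1L, t = use$t,
                            x0 = use$x0, y0 = use$y0, x1 = use$x1, y1 = use$y1,
                            sl = use$sl, ta = use$ta)
    avail_rows <- data.frame(stratum = idx, case = 0L, t = use$t[idx],
                             x0 = use$x0[idx], y0 = use$y0[idx], x1 = ex, y1 = ey,
                             sl = sl, ta = ta)
    out <- rbind(used_rows, avail_rows)
    out <- out[order(out$stratum, -out$case), , drop = FALSE]
    if (any(out$sl <= 0)) out$sl[out$sl <= 0] <- min(out$sl[out$sl > 0]) / 2
    out$log_sl <- log(out$sl)
    out$cos_ta <- cos(out$ta)
    rownames(out) <- NULL
    class(out) <- c("step_set", "data.frame")
    out
  })
}

#' Attach start- and end-point covariates to a step set
#'
#' Extracts raw covariates at both endpoints and standardizes the habitat
#' covariates. Movement terms (SL, lnSL, cos TA) stay on their natural scale
#' so the gamma-kernel adjustment algebra holds. The standardization
#' reference defaults to the union of used and available records in
#' \code{step_set}; pass a precomputed table to share one scale across model
#' sets or bear-years.
#'
#' @param step_set output of \code{\link{generate_available_steps}}
#' @param stack a \code{landscape_stack}
#' @param year calendar year for the clearcut layer
#' @param std optional standardization table (covariate, mean, sd)
#' @return list with \code{data} (modeling data.frame: stratum, case,
#'   movement terms, *_end and *_start standardized covariates) and
#'   \code{std} (the table used)
#' @export
step_covariates <- function(step_set, stack, year = NULL, std = NULL) {
  covs <- c("bog", "clearcut", "tri", "log_dist_water", "log_dist_forestry",
            "log_dist_public", "log_dist_building")
  ce <- extract_covariates(stack, step_set$x1, step_set$y1, year = year)
  cs <- extract_covariates(stack, step_set$x0, step_set$y0, year = year)
  if (is.null(std)) std <- standardize_table(ce, covs)
  ce <- apply_standardization(ce, std)
  cs <- apply_standardization(cs, std)
  names(ce) <- paste0(names(ce), "_end")
  names(cs) <- paste0(names(cs), "_start")
  data <- cbind(step_set[, c("stratum", "case", "sl", "log_sl", "cos_ta")],
                ce[, paste0(covs, "_end")], cs[, paste0(covs, "_start")])
  list(data = data, std = std)
}

#' Conditional logistic regression for matched used/available steps
#'
#' Maximizes the stratified conditional log-likelihood
#' \deqn{\ell(\beta) = \sum_s [\eta_{used,s} - \ln \sum_j \exp(\eta_{js})]}
#' by Newton-Raphson with step halving; standard errors come from the
#' inverse observed information. Every stratum must contain exactly one used
#' step. The likelihood conditions out any stratum-constant covariate, so a
#' covariate constant within all strata makes the design deficient and is
#' reported as a rank error.
#'
#' @param data modeling data.frame with \code{stratum}, \code{case} and
#'   covariate columns (see \code{\link{step_covariates}})
#' @param terms model terms (see \code{\link{candidate_models}})
#' @param model_name label stored with the fit
#' @param bear_year_id identifier stored with the fit
#' @param max_iter,tol Newton iteration cap and gradient max-norm tolerance
#' @return object of class \code{issa_clogit}
#' @export
fit_clogit <- function(data, terms, model_name = "model",
                       bear_year_id = NA_character_, max_iter = 50, tol = 1e-9) {
  X <- build_design(data, terms)
  y <- data$case
  si <- as.integer(factor(data$stratum))
  ns <- max(si)
  if (any(tapply(y, si, sum) != 1)) stop("every stratum needs exactly 1 used step")
  # center within stratum: removes stratum-constant components and exposes
  # rank deficiency of the conditional design
  Xc <- X - rowsum(X, si)[si, , drop = FALSE] / tabulate(si)[si]
  qrx <- qr(Xc)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1, ncol(X))]]
    stop("conditional-logit design is rank deficient (covariate constant ",
         "within strata?): ", paste(bad, collapse = ", "))
  }
  # work on unit-spread columns so the information matrix stays well
  # conditioned (SL in meters spans orders of magnitude more than cos TA)
  scl <- apply(Xc, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(X, 2, scl, "/")
  beta <- rep(0, ncol(Xs))
  loglik <- function(eta) {
    mx <- as.numeric(tapply(eta, si, max))[si]
    ee <- exp(eta - mx)
    den <- rowsum(ee, si)
    sum(eta[y == 1]) - sum(mx[y == 1]) - sum(log(den))
  }
  ll <- loglik(drop(Xs %*% beta))
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(Xs %*% beta)
    mx <- as.numeric(tapply(eta, si, max))[si]
    ee <- exp(eta - mx)
    p <- as.numeric(ee / rowsum(ee, si)[si])
    grad <- drop(crossprod(Xs, y - p))
    M <- rowsum(Xs * p, si)
    info <- crossprod(Xs * sqrt(p), Xs * sqrt(p)) - crossprod(M)
    step <- tryCatch(solve(info, grad), error = function(e)
      stop("singular information matrix (separation or collinearity)"))
    # step halving to guarantee ascent
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      ll_new <- loglik(drop(Xs %*% beta_new))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) stop("conditional logit failed to converge (separation?)")
    }
    beta <- beta_new; ll <- ll_new
    if (max(abs(grad)) < tol || iter >= max_iter) break
  }
  if (max(abs(grad)) > 1e-4)
    stop("conditional logit did not converge: max |score| = ", signif(max(abs(grad)), 3))
  beta <- beta / scl
  names(beta) <- colnames(X)
  vc <- solve(info) / outer(scl, scl)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    bear_year_id = bear_year_id, model_name = model_name, terms = terms,
    coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
    log_likelihood = ll, aic = 2 * length(beta) - 2 * ll,
    n_strata = ns, n_obs = length(y), iterations = iter,
    score_norm = max(abs(grad)), converged = TRUE), class = "issa_clogit")
}

#' @export
print.issa_clogit <- function(x, ...) {
  cat(sprintf("<issa_clogit> %s / %s: %d strata (%d rows), logLik %.2f, AIC %.2f\n",
              x$bear_year_id, x$model_name, x$n_strata, x$n_obs,
              x$log_likelihood, x$aic))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
summary.issa_clogit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(estimate = object$coefficients, se = object$se, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               ci_low = object$coefficients - 1.96 * object$se,
               ci_high = object$coefficients + 1.96 * object$se)
  structure(list(fit = object, table = tab), class = "summary.issa_clogit")
}

#' @export
print.summary.issa_clogit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
coef.issa_clogit <- function(object, ...) object$coefficients

#' @export
vcov.issa_clogit <- function(object, ...) object$vcov

#' @export
logLik.issa_clogit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients), class = "logLik")
}

#' @export
AIC.issa_clogit <- function(object, ..., k = 2) {
  k * length(object$coefficients) - 2 * object$log_likelihood
}
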