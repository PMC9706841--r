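#' Step lengths and turning angles from a track
#'
#' Converts consecutive hourly fixes into a step series. A step joins two
#' fixes exactly one hour apart (within tolerance); the turning angle is the
#' change of heading relative to the previous step and is \code{NA} for the
#' first step of each contiguous run (after any gap).
#'
#' @param track time-ordered track data.frame (columns t, x, y)
#' @param tolerance_s slack on the 1-h step duration, seconds
#' @return data.frame with columns t (step start), x0, y0, x1, y1, sl
#'   (meters), heading (radians), ta (radians, NA where undefined)
#' @export
movement_steps <- function(track, tolerance_s = 180) {
  n <- nrow(track)
  if (n < 2) return(data.frame(t = track$t[0], x0 = numeric(0), y0 = numeric(0),
                               x1 = numeric(0), y1 = numeric(0), sl = numeric(0),
                               heading = numeric(0), ta = numeric(0)))
  dt <- as.numeric(diff(track$t), units = "secs")
  ok <- abs(dt - 3600) <= tolerance_s
  i0 <- which(ok)
  dx <- track$x[i0 + 1] - track$x[i0]
  dy <- track$y[i0 + 1] - track$y[i0]
  st <- data.frame(t = track$t[i0], x0 = track$x[i0], y0 = track$y[i0],
                   x1 = track$x[i0 + 1], y1 = track$y[i0 + 1],
                   sl = sqrt(dx^2 + dy^2), heading = atan2(dy, dx))
  # turning angle defined only when the previous step ends where this begins
  prev_contig <- c(FALSE, diff(i0) == 1)
  ta <- rep(NA_real_, nrow(st))
  if (nrow(st) > 1) {
    d <- st$heading[-1] - st$heading[-nrow(st)]
    ta[-1] <- atan2(sin(d), cos(d))
  }
  ta[!prev_contig] <- NA_real_
  st$ta <- ta
  st
}

#' Candidate HMM specifications
#'
#' The default candidate set: one 1-state model, and 2- and 3-state models
#' with three initializations each, spaced by quantiles of the observed step
#' lengths (seven specifications in total).
#'
#' @param sl observed step lengths (meters)
#' @return list of spec lists (n_states, shape0, scale0, mu0, kappa0, label)
#' @export
hmm_candidate_specs <- function(sl) {
  sl <- sl[is.finite(sl) & sl > 0]
  q <- function(p) stats::quantile(sl, p, names = FALSE)
  mk <- function(K, means, label) {
    list(n_states = K, shape0 = rep(1.5, K), scale0 = means / 1.5,
         mu0 = rep(0, K), kappa0 = seq(0.3, 1, length.out = K), label = label)
  }
  list(
    mk(1, q(0.5), "1state"),
    mk(2, q(c(0.25, 0.75)), "2state_q25_75"),
    mk(2, q(c(0.10, 0.90)), "2state_q10_90"),
    mk(2, q(c(0.40, 0.95)), "2state_q40_95"),
    mk(3, q(c(0.20, 0.50, 0.80)), "3state_q20_50_80"),
    mk(3, q(c(0.10, 0.50, 0.90)), "3state_q10_50_90"),
    mk(3, q(c(0.25, 0.60, 0.95)), "3state_q25_60_95"))
}

# ---- working-parameter transforms ----------------------------------------

hmm_pack <- function(shape, scale, mu, kappa, trans) {
  K <- length(shape)
  p <- c(log(shape), log(scale), 2 * tan(mu / 2), log(pmax(kappa, 1e-6)))
  if (K > 1) {
    off <- log(trans / diag(trans))  # row-wise logit vs diagonal baseline
    p <- c(p, off[row(off) != col(off)])
  }
  p
}

hmm_unpack <- function(p, K) {
  shape <- exp(p[1:K]); scale <- exp(p[K + 1:K])
  mu <- 2 * atan(p[2 * K + 1:K] / 2); kappa <- exp(p[3 * K + 1:K])
  if (K == 1) {
    trans <- matrix(1, 1, 1)
  } else {
    off <- p[4 * K + seq_len(K * (K - 1))]
    M <- diag(K) * 0
    M[row(matrix(0, K, K)) != col(matrix(0, K, K))] <- off
    E <- exp(M); diag(E) <- 1
    trans <- E / rowSums(E)
  }
  list(shape = shape, scale = scale, mu = mu, kappa = kappa, trans = trans)
}

# State-dependent density matrix (n x K) for step lengths and turning angles;
# NA turning angles contribute only the gamma factor.
hmm_dens <- function(sl, ta, par) {
  K <- length(par$shape)
  n <- length(sl)
  dens <- matrix(0, n, K)
  has_ta <- !is.na(ta)
  for (k in seq_len(K)) {
    d <- suppressWarnings(stats::dgamma(sl, shape = par$shape[k], scale = par$scale[k]))
    d[is.nan(d)] <- 0
    d[has_ta] <- d[has_ta] * dvonmises(ta[has_ta], par$mu[k], par$kappa[k])
    dens[, k] <- d
  }
  dens
}

#' Fit a hidden Markov movement model by direct likelihood maximization
#'
#' State-dependent gamma step lengths and von Mises turning angles; the
#' forward-algorithm likelihood is maximized numerically (BFGS on working
#' parameters: log shapes/scales/concentrations, transformed angle means,
#' multinomial-logit transition rows). The initial state distribution is the
#' stationary distribution of the transition matrix. Zero step lengths are
#' replaced by half the minimum positive length before evaluation.
#'
#' @param steps data.frame from \code{\link{movement_steps}} (columns sl, ta)
#' @param spec specification list (n_states, shape0, scale0, mu0, kappa0,
#'   label), e.g. one element of \code{\link{hmm_candidate_specs}}
#' @param max_iter maximum optimizer iterations
#' @param tol relative convergence tolerance
#' @param seed seed for the small random jitter applied to initial values
#' @return object of class \code{bear_hmm}: parameters, transition matrix,
#'   stationary initial distribution, log-likelihood, AIC, convergence flag,
#'   decoded states (Viterbi), and the data
#' @export
fit_hmm <- function(steps, spec, max_iter = 300, tol = 1e-9, seed = 1L) {
  sl <- steps$sl; ta <- steps$ta
  if (length(sl) < 3) stop("need at least 3 steps to fit an HMM")
  if (any(sl <= 0)) {
    halfmin <- min(sl[sl > 0]) / 2
    sl[sl <= 0] <- halfmin
  }
  K <- spec$n_states
  init_trans <- matrix(0.1 / max(1, K - 1), K, K); diag(init_trans) <- 0.9
  if (K == 1) init_trans <- matrix(1, 1, 1)
  p0 <- hmm_pack(spec$shape0, spec$scale0, spec$mu0, spec$kappa0, init_trans)
  negll <- function(p) {
    par <- hmm_unpack(p, K)
    dens <- hmm_dens(sl, ta, par)
    delta <- if (K == 1) 1 else stationary_dist(par$trans)
    -forward_loglik_cpp(dens, par$trans, delta)
  }
  opt <- with_seed(seed, {
    p0j <- p0 + stats::rnorm(length(p0), 0, 0.01)
    stats::optim(p0j, negll, method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol))
  })
  par <- hmm_unpack(opt$par, K)
  ll <- -opt$value
  k_par <- 4 * K + K * (K - 1)
  fit <- structure(list(
    spec = spec, n_states = K,
    shape = par$shape, scale = par$scale, mu = par$mu, kappa = par$kappa,
    transition = par$trans,
    delta = if (K == 1) 1 else stationary_dist(par$trans),
    log_likelihood = ll, n_parameters = k_par,
    aic = 2 * k_par - 2 * ll,
    converged = opt$convergence == 0 && is.finite(ll),
    sl = sl, ta = ta), class = "bear_hmm")
  fit$decoded_states <- viterbi(fit)
  fit
}

#' @export
print.bear_hmm <- function(x, ...) {
  cat(sprintf("<bear_hmm> %d state(s), logLik %.3f, AIC %.3f%s\n", x$n_states,
              x$log_likelihood, x$aic, if (x$converged) "" else " (NOT converged)"))
  for (k in seq_len(x$n_states))
    cat(sprintf("  state %d: gamma(shape %.3f, scale %.1f m; mean %.0f m), vonMises(mu %.2f, kappa %.2f)\n",
                k, x$shape[k], x$scale[k], x$shape[k] * x$scale[k], x$mu[k], x$kappa[k]))
  if (x$n_states > 1) {
    cat("  transition matrix:\n")
    print(round(x$transition, 3))
  }
  invisible(x)
}

#' @export
logLik.bear_hmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters, class = "logLik")
}

#' @export
AIC.bear_hmm <- function(object, ..., k = 2) {
  k * object$n_parameters - 2 * object$log_likelihood
}

#' Forward-algorithm log-likelihood of a fitted HMM
#' @param fit a \code{bear_hmm}
#' @param sl,ta optional alternative data (defaults: the fitting data)
#' @return log-likelihood value
#' @export
hmm_loglik <- function(fit, sl = fit$sl, ta = fit$ta) {
  par <- list(shape = fit$shape, scale = fit$scale, mu = fit$mu,
              kappa = fit$kappa, trans = fit$transition)
  forward_loglik_cpp(hmm_dens(sl, ta, par), fit$transition,
                     as.numeric(fit$delta))
}

#' Most probable state sequence (Viterbi decoding)
#'
#' @param fit a \code{bear_hmm}
#' @param sl,ta optional alternative data (defaults: the fitting data)
#' @return integer vector of decoded states, one per step
#' @export
viterbi <- function(fit, sl = fit$sl, ta = fit$ta) {
  K <- fit$n_states
  n <- length(sl)
  if (K == 1) return(rep(1L, n))
  par <- list(shape = fit$shape, scale = fit$scale, mu = fit$mu,
              kappa = fit$kappa, trans = fit$transition)
  ldens <- log(hmm_dens(sl, ta, par))
  ltr <- log(fit$transition)
  v <- log(as.numeric(fit$delta)) + ldens[1, ]
  back <- matrix(0L, n, K)
  for (i in 2:n) {
    cand <- v + ltr  # cand[j, k] = v[j] + log trans[j, k]
    back[i, ] <- max.col(t(cand), ties.method = "first")
    v <- cand[cbind(back[i, ], seq_len(K))] + ldens[i, ]
  }
  states <- integer(n)
  states[n] <- which.max(v)
  for (i in n:2) states[i - 1] <- back[i, states[i]]
  states
}

#' Fit a set of candidate HMMs and select by AIC
#'
#' Fits every candidate specification, drops non-converged fits (with a
#' warning), and returns the minimum-AIC fit; exact ties go to the model
#' with fewer states.
#'
#' @param steps step series (\code{\link{movement_steps}})
#' @param specs list of specifications; default
#'   \code{\link{hmm_candidate_specs}} on the observed step lengths
#' @param seed seed passed to each fit
#' @return the selected \code{bear_hmm}, with the full fit list in
#'   \code{$candidates}
#' @export
select_hmm <- function(steps, specs = NULL, seed = 1L) {
  if (is.null(specs)) specs <- hmm_candidate_specs(steps$sl)
  fits <- lapply(seq_along(specs), function(i) {
    tryCatch(fit_hmm(steps, specs[[i]], seed = seed + i),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  ok[ok] <- vapply(fits[ok], function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("all candidate HMM fits failed")
  if (any(!ok)) warning(sum(!ok), " candidate fit(s) excluded (failed or not converged)")
  fits_ok <- fits[ok]
  aic <- vapply(fits_ok, `[[`, 0, "aic")
  ns <- vapply(fits_ok, function(f) as.integer(f$n_states), 0L)
  best <- order(aic, ns)[1]
  out <- fits_ok[[best]]
  out$candidates <- data.frame(
    label = vapply(fits_ok, function(f) f$spec$label, ""),
    n_states = ns, aic = aic, logLik = vapply(fits_ok, `[[`, 0, "log_likelihood"))
  out
}

#' Delineate the single dispersal window from decoded states
#'
#' Runs of the transit state (by default the state with the largest mean
#' step length) separated by gaps of at most \code{max_gap_h} hours are
#' merged; the longest merged run whose duration reaches \code{min_run_h}
#' hours becomes the dispersal window. At most one window is returned.
#'
#' @param states decoded state sequence (one per step)
#' @param timestamps POSIXct step start times, same length
#' @param transit_state the transit state index; default: largest-mean state
#'   of \code{fit} when supplied, else \code{max(states)}
#' @param fit optional \code{bear_hmm} used to identify the transit state
#' @param min_run_h minimum window duration, hours
#' @param max_gap_h maximum within-window gap, hours
#' @return list(onset, end) of class \code{dispersal_window}, or NULL when no
#'   qualifying run exists
#' @export
delineate_dispersal <- function(states, timestamps, transit_state = NULL,
                                fit = NULL, min_run_h = 7 * 24, max_gap_h = 48) {
  stopifnot(length(states) == length(timestamps))
  if (is.null(transit_state)) {
    transit_state <- if (!is.null(fit)) which.max(fit$shape * fit$scale)
                     else max(states)
  }
  idx <- which(states == transit_state)
  if (!length(idx)) return(NULL)
  tt <- as.numeric(timestamps[idx])
  brk <- which(diff(tt) > max_gap_h * 3600)
  grp <- cumsum(c(0, seq_along(tt)[-1] %in% (brk + 1)))
  windows <- do.call(rbind, lapply(split(tt, grp), range))
  dur <- (windows[, 2] - windows[, 1]) / 3600
  keep <- which(dur >= min_run_h)
  if (!length(keep)) return(NULL)
  w <- keep[which.max(dur[keep])]
  structure(list(onset = as.POSIXct(unname(windows[w, 1]), origin = "1970-01-01", tz = "UTC"),
                 end = as.POSIXct(unname(windows[w, 2]), origin = "1970-01-01", tz = "UTC")),
            class = "dispersal_window")
}

#' @export
print.dispersal_window <- function(x, ...) {
  cat(sprintf("<dispersal_window> %s to %s (%.1f days)\n",
              format(x$onset), format(x$end),
              as.numeric(difftime(x$end, x$onset, units = "days"))))
  invisible(x)
}
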