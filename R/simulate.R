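#' Ground-truth movement kernel for simulation
#'
#' Parameters of the generative step-selection kernel: habitat selection
#' coefficients on (standardized) end-point covariates, movement coefficients
#' on step length and its log, interactions of log step length with
#' (standardized) start-point covariates, the tentative gamma step-length
#' distribution (meters), and the von Mises turning-angle concentration.
#'
#' The implied realized step-length kernel is gamma with shape
#' \code{tentative_shape + beta_log_sl + sum(beta_log_sl_start * x_start)} and
#' rate \code{1/tentative_scale - beta_sl}; both must stay positive over the
#' simulated covariate range.
#'
#' @param beta_habitat named numeric vector of end-point selection
#'   coefficients (names are covariate names on the standardized scale)
#' @param beta_sl coefficient on step length (per meter)
#' @param beta_log_sl coefficient on ln step length
#' @param beta_log_sl_start named numeric vector of ln(SL) x start-covariate
#'   interaction coefficients
#' @param tentative_shape,tentative_scale gamma parameters of the tentative
#'   step-length distribution (scale in meters)
#' @param kappa von Mises turning-angle concentration, >= 0
#' @return a \code{kernel_truth} object
#' @export
kernel_truth <- function(beta_habitat = c(bog = -0.9),
                         beta_sl = 0,
                         beta_log_sl = 0,
                         beta_log_sl_start = c(log_dist_forestry = 0),
                         tentative_shape = 2,
                         tentative_scale = 300,
                         kappa = 0.5) {
  stopifnot(tentative_shape > 0, tentative_scale > 0, kappa >= 0)
  if (1 / tentative_scale - beta_sl <= 0)
    stop("adjusted rate 1/scale - beta_sl must be positive")
  structure(list(beta_habitat = beta_habitat, beta_sl = beta_sl,
                 beta_log_sl = beta_log_sl, beta_log_sl_start = beta_log_sl_start,
                 tentative_shape = tentative_shape, tentative_scale = tentative_scale,
                 kappa = kappa),
            class = "kernel_truth")
}

#' @export
print.kernel_truth <- function(x, ...) {
  cat("<kernel_truth> tentative gamma(shape =", x$tentative_shape,
      ", scale =", x$tentative_scale, "m), kappa =", x$kappa, "\n")
  cat("  habitat:", paste(names(x$beta_habitat), signif(x$beta_habitat, 3),
                          sep = " = ", collapse = ", "), "\n")
  cat("  movement: beta_sl =", x$beta_sl, ", beta_log_sl =", x$beta_log_sl, "\n")
  cat("  lnSL x start:", paste(names(x$beta_log_sl_start),
                               signif(x$beta_log_sl_start, 3),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# Standardized layer values at cell indices for the named covariates.
std_layer_values <- function(stack, idx, covs, std) {
  out <- matrix(NA_real_, nrow(idx), length(covs), dimnames = list(NULL, covs))
  for (v in covs) {
    i <- match(v, std$covariate)
    if (is.na(i)) stop("covariate not in standardization table: ", v)
    out[, v] <- (stack$layers[[v]][idx] - std$mean[i]) / std$sd[i]
  }
  out
}

#' Simulate a trajectory from a known step-selection kernel
#'
#' At each hourly step, \code{n_candidates} candidate endpoints are drawn
#' with lengths from the tentative gamma and turning angles from a von Mises
#' around the previous heading; one is selected with probability proportional
#' to \code{exp(selection score)} under the ground-truth kernel. Candidates
#' falling outside the landscape are redrawn (up to \code{max_retry} rounds).
#'
#' @param stack a \code{landscape_stack}
#' @param truth a \code{\link{kernel_truth}}
#' @param n_steps number of steps (track has \code{n_steps + 1} fixes)
#' @param start numeric length-2 start coordinate (meters); default: landscape
#'   center
#' @param seed integer seed
#' @param bear_year_id identifier attached to the fixes
#' @param t0 POSIXct timestamp of the first fix
#' @param n_candidates candidate endpoints per step
#' @param std standardization table defining the scale of the truth
#'   coefficients; default: the stack's landscape-wide table
#' @param max_retry redraw rounds before giving up on a step
#' @return list with \code{track} (data.frame: bear_year_id, t, x, y, dop) and
#'   \code{truth}
#' @export
simulate_issa_track <- function(stack, truth, n_steps, start = NULL, seed = 1L,
                                bear_year_id = "sim_1",
                                t0 = as.POSIXct("2015-05-01 00:00:00", tz = "UTC"),
                                n_candidates = 200L, std = stack$std,
                                max_retry = 100L) {
  stopifnot(inherits(stack, "landscape_stack"), inherits(truth, "kernel_truth"),
            n_steps >= 1)
  ext <- c(stack$xmin, stack$xmin + stack$nx * stack$res,
           stack$ymin, stack$ymin + stack$ny * stack$res)
  if (is.null(start)) start <- c(mean(ext[1:2]), mean(ext[3:4]))
  if (!raster_inside(stack, start[1], start[2])) stop("start outside landscape")
  # truth coefficients may be named with the modeling suffixes (_end/_start);
  # the landscape layers carry the base names
  hab_covs <- sub("_end$", "", names(truth$beta_habitat))
  start_covs <- sub("_start$", "", names(truth$beta_log_sl_start))
  with_seed(seed, {
    x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
    x[1] <- start[1]; y[1] <- start[2]
    heading <- stats::runif(1, -pi, pi)
    for (i in seq_len(n_steps)) {
      # start covariates fixed for the stratum
      sidx <- cell_index(stack, x[i], y[i], what = "start point")
      xs <- std_layer_values(stack, cbind(sidx$ix, sidx$iy), start_covs, std)
      for (try in seq_len(max_retry)) {
        sl <- stats::rgamma(n_candidates, shape = truth$tentative_shape,
                            scale = truth$tentative_scale)
        ta <- rvonmises(n_candidates, 0, truth$kappa)
        ang <- heading + ta
        ex <- x[i] + sl * cos(ang); ey <- y[i] + sl * sin(ang)
        ok <- raster_inside(stack, ex, ey)
        if (any(ok)) break
        if (try == max_retry) stop("candidate set entirely outside landscape at step ", i)
      }
      sl <- sl[ok]; ang <- ang[ok]; ex <- ex[ok]; ey <- ey[ok]
      eidx <- cell_index(stack, ex, ey, what = "endpoint")
      he <- std_layer_values(stack, cbind(eidx$ix, eidx$iy), hab_covs, std)
      eta <- drop(he %*% truth$beta_habitat) + truth$beta_sl * sl +
        (truth$beta_log_sl + drop(xs %*% truth$beta_log_sl_start)) * log(sl)
      w <- exp(eta - max(eta))
      j <- sample.int(length(sl), 1, prob = w)
      x[i + 1] <- ex[j]; y[i + 1] <- ey[j]
      heading <- ang[j]
    }
    track <- data.frame(bear_year_id = bear_year_id,
                        t = t0 + 3600 * (0:n_steps), x = x, y = y, dop = 2)
    list(track = track, truth = truth)
  })
}

#' Simulate a trajectory from a hidden Markov movement model
#'
#' Draws a latent Markov state sequence, then state-dependent gamma step
#' lengths and von Mises turning angles, and integrates them into
#' coordinates with hourly timestamps. The latent sequence is returned for
#' recovery tests.
#'
#' @param states list of per-state parameter lists with elements
#'   \code{shape}, \code{scale} (gamma, meters) and \code{mu}, \code{kappa}
#'   (von Mises turning angle)
#' @param transition square transition matrix (rows sum to 1)
#' @param n_steps number of steps
#' @param seed integer seed
#' @param start start coordinate
#' @param initial_state optional fixed initial state (default: stationary draw)
#' @param bear_year_id,t0 identifier and first timestamp
#' @return list with \code{track}, \code{states} (latent sequence, one per
#'   step), \code{sl} and \code{ta}
#' @export
simulate_hmm_track <- function(states, transition, n_steps, seed = 1L,
                               start = c(0, 0), initial_state = NULL,
                               bear_year_id = "sim_hmm",
                               t0 = as.POSIXct("2015-05-01 00:00:00", tz = "UTC")) {
  K <- length(states)
  transition <- as.matrix(transition)
  if (nrow(transition) != K || ncol(transition) != K ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition must be a ", K, "x", K, " stochastic matrix (rows sum to 1)")
  for (s in states)
    stopifnot(s$shape > 0, s$scale > 0, s$kappa >= 0)
  with_seed(seed, {
    st <- integer(n_steps)
    st[1] <- if (!is.null(initial_state)) initial_state
             else sample.int(K, 1, prob = stationary_dist(transition))
    if (n_steps > 1)
      for (i in 2:n_steps) st[i] <- sample.int(K, 1, prob = transition[st[i - 1], ])
    shp <- vapply(states, `[[`, 0, "shape")[st]
    scl <- vapply(states, `[[`, 0, "scale")[st]
    sl <- stats::rgamma(n_steps, shape = shp, scale = scl)
    ta <- numeric(n_steps)
    for (k in seq_len(K)) {
      sel <- st == k
      if (any(sel)) ta[sel] <- rvonmises(sum(sel), states[[k]]$mu, states[[k]]$kappa)
    }
    # absolute headings: first heading random, then previous heading + turn
    abs_ang <- numeric(n_steps)
    abs_ang[1] <- stats::runif(1, -pi, pi)
    if (n_steps > 1) for (i in 2:n_steps) abs_ang[i] <- abs_ang[i - 1] + ta[i]
    x <- cumsum(c(start[1], sl * cos(abs_ang)))
    y <- cumsum(c(start[2], sl * sin(abs_ang)))
    track <- data.frame(bear_year_id = bear_year_id,
                        t = t0 + 3600 * (0:n_steps), x = x, y = y, dop = 2)
    list(track = track, states = st, sl = sl, ta = ta)
  })
}

# Stationary distribution of a stochastic matrix.
stationary_dist <- function(G) {
  K <- nrow(G)
  A <- rbind(t(diag(K) - G), rep(1, K))
  b <- c(rep(0, K), 1)
  sol <- stats::lm.fit(A, b)$coefficients
  p <- pmax(sol, 0); p / sum(p)
}

#' Inject telemetry artifacts into a clean simulated track
#'
#' Emulates field-data blemishes with a known oracle: resting (bed-site)
#' clusters are created by collapsing runs of consecutive fixes onto a
#' jittered cluster center; DOP values are assigned with a stated fraction
#' above 10; fixes are deleted to create gaps. The returned log records
#' exactly what was injected.
#'
#' @param track data.frame with columns t, x, y (and optionally dop)
#' @param bed_cluster_spec list(n_clusters, n_fixes, radius_m) or NULL
#' @param dop_spec list(frac_high, base = c(1, 6), high = c(10.5, 20)) or NULL
#' @param gap_spec list(n_gaps, gap_len) or NULL
#' @param seed integer seed
#' @return list with \code{track} (modified) and \code{log} (list with
#'   \code{bed_clusters}: list of integer index vectors into the returned
#'   track's rows before gap deletion, \code{high_dop_idx}, \code{gap_idx})
#' @export
inject_artifacts <- function(track, bed_cluster_spec = NULL, dop_spec = NULL,
                             gap_spec = NULL, seed = 1L) {
  with_seed(seed, {
    n <- nrow(track)
    log <- list(bed_clusters = list(), high_dop_idx = integer(0), gap_idx = integer(0))
    if (!is.null(bed_cluster_spec)) {
      nc <- bed_cluster_spec$n_clusters %||% 1L
      nf <- bed_cluster_spec$n_fixes %||% 6L
      rad <- bed_cluster_spec$radius_m %||% 10
      used <- rep(FALSE, n)
      for (k in seq_len(nc)) {
        # pick a run not touching an existing cluster (with a gap fix on each side)
        cand <- which(!used)
        ok_start <- cand[cand + nf - 1 <= n]
        ok_start <- ok_start[vapply(ok_start, function(s) !any(used[max(1, s - 1):min(n, s + nf)]), TRUE)]
        if (!length(ok_start)) break
        s <- sample(ok_start, 1)
        idx <- s:(s + nf - 1)
        cx <- track$x[s]; cy <- track$y[s]
        r <- rad * sqrt(stats::runif(nf)) / sqrt(2)  # jitter well within radius
        a <- stats::runif(nf, 0, 2 * pi)
        # clamp to the track bounding box so jitter cannot leave the landscape
        track$x[idx] <- pmin(pmax(cx + r * cos(a), min(track$x)), max(track$x))
        track$y[idx] <- pmin(pmax(cy + r * sin(a), min(track$y)), max(track$y))
        used[idx] <- TRUE
        log$bed_clusters[[length(log$bed_clusters) + 1]] <- idx
      }
    }
    if (!is.null(dop_spec)) {
      base <- dop_spec$base %||% c(1, 6)
      high <- dop_spec$high %||% c(10.5, 20)
      track$dop <- stats::runif(n, base[1], base[2])
      nh <- round((dop_spec$frac_high %||% 0) * n)
      if (nh > 0) {
        hi <- sample.int(n, nh)
        track$dop[hi] <- stats::runif(nh, high[1], high[2])
        log$high_dop_idx <- sort(hi)
      }
    }
    if (!is.null(gap_spec)) {
      ng <- gap_spec$n_gaps %||% 0L
      gl <- gap_spec$gap_len %||% 1L
      if (ng > 0) {
        protected <- unlist(log$bed_clusters)
        starts <- setdiff(2:(n - gl), protected)
        if (length(starts)) {
          ss <- sample(starts, min(ng, length(starts)))
          gi <- sort(unique(unlist(lapply(ss, function(s) s:(s + gl - 1)))))
          gi <- setdiff(gi, protected)
          log$gap_idx <- gi
          track <- track[-gi, , drop = FALSE]
          rownames(track) <- NULL
        }
      }
    }
    list(track = track, log = log)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write tracks to CSV (id, ISO-8601 timestamp, x, y, dop)
#' @param track track data.frame
#' @param path output file
#' @export
write_track_csv <- function(track, path) {
  out <- data.frame(id = track$bear_year_id,
                    timestamp = format(track$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    x = track$x, y = track$y, dop = track$dop)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks written by \code{write_track_csv}
#' @param path CSV file
#' @return track data.frame (bear_year_id, t, x, y, dop)
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(bear_year_id = d$id,
             t = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             x = d$x, y = d$y, dop = d$dop)
}
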