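#' Resample fixes to an hourly grid
#'
#' Keeps at most one fix per top-of-the-hour grid time: the fix nearest to
#' the grid time among those within the tolerance. The grid is anchored at
#' minute zero.
#'
#' @param track data.frame with columns t (POSIXct), x, y (and others kept)
#' @param tolerance_s half-width of the acceptance window, seconds
#' @return the track restricted to retained fixes, time-sorted
#' @export
resample_hourly <- function(track, tolerance_s = 180) {
  if (nrow(track) == 0) return(track)
  track <- track[order(track$t), , drop = FALSE]
  tt <- as.numeric(track$t)
  grid <- round(tt / 3600) * 3600
  off <- abs(tt - grid)
  ok <- off <= tolerance_s
  cand <- track[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  g <- grid[ok]; o <- off[ok]
  keep <- unlist(lapply(split(seq_len(nrow(cand)), g), function(i) i[which.min(o[i])]))
  out <- cand[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove fixes with high dilution of precision
#'
#' Retains fixes with DOP strictly below \code{max_dop}; a fix at exactly the
#' threshold is removed. Missing DOP is retained with a warning by default.
#'
#' @param track track data.frame with a \code{dop} column
#' @param max_dop threshold; fixes with \code{dop >= max_dop} are removed
#' @param missing how to treat missing DOP: "retain" (default, warns) or "drop"
#' @return filtered track
#' @export
filter_dop <- function(track, max_dop = 10, missing = c("retain", "drop")) {
  missing <- match.arg(missing)
  if (is.null(track$dop)) {
    warning("no dop column; retaining all fixes")
    return(track)
  }
  na <- is.na(track$dop)
  if (any(na) && missing == "retain") warning(sum(na), " fixes with missing DOP retained")
  keep <- if (missing == "retain") na | track$dop < max_dop else !na & track$dop < max_dop
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect bed-site (resting) clusters
#'
#' Greedy left-to-right scan over the time-ordered fixes: a candidate run is
#' extended while the new fix is (a) within \code{max_consecutive_m} of the
#' previous fix and (b) within \code{max_pairwise_m} of every fix already in
#' the run. Runs of at least \code{min_fixes} fixes (i.e. at least 4 h at one
#' location for hourly data and the default 5) are emitted as bed sites.
#' Clusters are maximal and non-overlapping: after a run ends, the scan
#' resumes at the first fix after it.
#'
#' @param track time-ordered track data.frame
#' @param max_pairwise_m maximum distance between any two fixes in a cluster
#' @param max_consecutive_m maximum distance between consecutive fixes
#' @param min_fixes minimum number of consecutive fixes in a cluster
#' @return list of integer vectors (row indices of each cluster)
#' @export
detect_bed_sites <- function(track, max_pairwise_m = 50, max_consecutive_m = 30,
                             min_fixes = 5) {
  n <- nrow(track)
  clusters <- list()
  i <- 1L
  while (i <= n) {
    run <- i
    j <- i + 1L
    while (j <= n) {
      d_prev <- sqrt((track$x[j] - track$x[j - 1])^2 + (track$y[j] - track$y[j - 1])^2)
      if (d_prev > max_consecutive_m) break
      d_all <- sqrt((track$x[run] - track$x[j])^2 + (track$y[run] - track$y[j])^2)
      if (any(d_all > max_pairwise_m)) break
      run <- c(run, j)
      j <- j + 1L
    }
    if (length(run) >= min_fixes) {
      clusters[[length(clusters) + 1]] <- run
      i <- run[length(run)] + 1L
    } else {
      i <- i + 1L
    }
  }
  clusters
}

#' Flag bed-site fixes on a track
#'
#' Runs \code{\link{detect_bed_sites}} and adds/updates a logical
#' \code{bed_site} column. Idempotent: re-flagging a flagged track changes
#' nothing.
#'
#' @inheritParams detect_bed_sites
#' @return track with a \code{bed_site} column
#' @export
flag_bed_sites <- function(track, max_pairwise_m = 50, max_consecutive_m = 30,
                           min_fixes = 5) {
  cl <- detect_bed_sites(track, max_pairwise_m, max_consecutive_m, min_fixes)
  track$bed_site <- FALSE
  if (length(cl)) track$bed_site[unlist(cl)] <- TRUE
  track
}

#' Remove fixes overlaying water
#'
#' Drops fixes whose containing raster cell is water. Fixes outside the
#' raster raise an error naming the offending fix.
#'
#' @param track track data.frame
#' @param water a \code{bm_raster} with 1 = water, or a \code{landscape_stack}
#' @return filtered track
#' @export
remove_water_fixes <- function(track, water) {
  if (inherits(water, "landscape_stack")) water <- stack_layer(water, "water")
  if (nrow(track) == 0) return(track)
  v <- raster_lookup(water, track$x, track$y, what = "fix")
  out <- track[v != 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clip a bear-year to the active period and check day coverage
#'
#' The active period runs 25 April to 20 August (118 days, inclusive).
#' Residents are clipped to the window and rejected when fewer than
#' \code{min_day_coverage} of the window days carry at least one fix.
#' Dispersers are clipped to their dispersal window, permitting at most
#' \code{max_outside_days} calendar days outside the active period (extra
#' outside days are trimmed from the window edges).
#'
#' @param track track data.frame
#' @param life_stage "resident" or "disperser"
#' @param start,end month-day strings bounding the active period
#' @param min_day_coverage minimum fraction of window days with a fix
#'   (residents)
#' @param dispersal_window POSIXct length-2 (onset, end); required for
#'   dispersers
#' @param max_outside_days days of disperser data allowed outside the active
#'   period
#' @return the clipped track, or \code{NULL} when a resident bear-year fails
#'   the coverage criterion
#' @export
apply_active_period <- function(track, life_stage = c("resident", "disperser"),
                                start = "04-25", end = "08-20",
                                min_day_coverage = 0.70,
                                dispersal_window = NULL,
                                max_outside_days = 6) {
  life_stage <- match.arg(life_stage)
  if (nrow(track) == 0) return(if (life_stage == "resident") NULL else track)
  yr <- format(track$t[1], "%Y")
  w0 <- as.POSIXct(paste0(yr, "-", start, " 00:00:00"), tz = "UTC")
  w1 <- as.POSIXct(paste0(yr, "-", end, " 23:59:59"), tz = "UTC")
  if (life_stage == "resident") {
    inw <- track$t >= w0 & track$t <= w1
    clipped <- track[inw, , drop = FALSE]
    n_days <- as.integer(as.Date(as.character(w1)) - as.Date(as.character(w0))) + 1L
    covered <- length(unique(as.Date(clipped$t)))
    if (covered / n_days < min_day_coverage) return(NULL)
    rownames(clipped) <- NULL
    return(clipped)
  }
  if (is.null(dispersal_window)) stop("dispersal_window required for dispersers")
  d0 <- dispersal_window[1]; d1 <- dispersal_window[2]
  # trim the window so that no more than max_outside_days calendar days
  # fall outside the active period
  out_before <- max(0, as.numeric(as.Date(as.character(w0)) - as.Date(as.character(d0))))
  out_after <- max(0, as.numeric(as.Date(as.character(d1)) - as.Date(as.character(w1))))
  excess <- out_before + out_after - max_outside_days
  if (excess > 0) {
    trim_before <- min(out_before, ceiling(excess * out_before / (out_before + out_after)))
    trim_after <- min(out_after, excess - trim_before)
    d0 <- d0 + trim_before * 86400
    d1 <- d1 - trim_after * 86400
  }
  clipped <- track[track$t >= d0 & track$t <= d1, , drop = FALSE]
  rownames(clipped) <- NULL
  clipped
}

#' Run the full telemetry cleaning chain on one bear-year
#'
#' Hourly resampling, DOP filter, water removal, bed-site flagging, then the
#' active-period / day-coverage rule. Per-stage removal counts are attached
#' as the \code{"removal_log"} attribute.
#'
#' @param track raw track data.frame
#' @param stack \code{landscape_stack} supplying the water layer (or NULL to
#'   skip water removal)
#' @param life_stage "resident" or "disperser"
#' @param dispersal_window POSIXct length-2 for dispersers
#' @param max_dop DOP threshold
#' @param min_day_coverage resident coverage fraction
#' @return cleaned track with \code{bed_site} flags, or NULL if rejected
#' @export
preprocess_track <- function(track, stack = NULL,
                             life_stage = c("resident", "disperser"),
                             dispersal_window = NULL, max_dop = 10,
                             min_day_coverage = 0.70) {
  life_stage <- match.arg(life_stage)
  log <- c(raw = nrow(track))
  track <- resample_hourly(track); log["resampled"] <- nrow(track)
  track <- filter_dop(track, max_dop = max_dop); log["dop"] <- nrow(track)
  if (!is.null(stack)) track <- remove_water_fixes(track, stack)
  log["water"] <- nrow(track)
  track <- apply_active_period(track, life_stage = life_stage,
                               min_day_coverage = min_day_coverage,
                               dispersal_window = dispersal_window)
  if (is.null(track)) return(NULL)
  log["active_period"] <- nrow(track)
  track <- flag_bed_sites(track)
  log["bed_flagged"] <- sum(track$bed_site)
  attr(track, "removal_log") <- log
  attr(track, "life_stage") <- life_stage
  track
}
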