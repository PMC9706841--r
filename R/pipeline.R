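#' Ground-truth kernels emulating resident and disperser movement
#'
#' Study conditions for the synthetic integration study: habitat and
#' movement coefficients with the qualitative structure reported for male
#' brown bears (bog and clearcut avoidance, building avoidance expressed as
#' selection for larger building distances, faster movement closer to
#' roads), with dispersers taking longer, more directional steps.
#'
#' @param life_stage "resident" or "disperser"
#' @return a \code{\link{kernel_truth}}
#' @export
default_truth <- function(life_stage = c("resident", "disperser")) {
  life_stage <- match.arg(life_stage)
  if (life_stage == "resident") {
    kernel_truth(
      beta_habitat = c(bog_end = -0.65, clearcut_end = -0.42, tri_end = 0.02,
                       log_dist_water_end = 0.12, log_dist_building_end = 0.30,
                       log_dist_forestry_end = -0.06, log_dist_public_end = 0.09),
      beta_sl = 0, beta_log_sl = 0,
      beta_log_sl_start = c(clearcut_start = 0.12,
                            log_dist_forestry_start = -0.071,
                            log_dist_public_start = -0.022,
                            log_dist_building_start = 0.008),
      tentative_shape = 2, tentative_scale = 293, kappa = 0.5)
  } else {
    kernel_truth(
      beta_habitat = c(bog_end = -0.96, clearcut_end = -0.38, tri_end = 0.005,
                       log_dist_water_end = -0.02, log_dist_building_end = 0.30,
                       log_dist_forestry_end = -0.01, log_dist_public_end = 0.02),
      beta_sl = 0, beta_log_sl = 0,
      beta_log_sl_start = c(clearcut_start = 0.09,
                            log_dist_forestry_start = -0.070,
                            log_dist_public_start = -0.052,
                            log_dist_building_start = -0.032),
      tentative_shape = 2, tentative_scale = 365, kappa = 1.5)
  }
}

#' Pipeline configuration
#'
#' All thresholds and study-design parameters of the synthetic end-to-end
#' study in one place. Defaults are the analysis defaults throughout the
#' package: hourly fixes, DOP < 10, 50/30 m and 5-fix bed rule, 25 April to
#' 20 August active period with 70% day coverage, 18-km MCP buffer, 20:1
#' availability at both scales, 95% CIs with normal multiplier.
#'
#' @param seed master seed; per-stage seeds are derived from it
#' @param n_residents,n_dispersers number of simulated bear-years
#' @param resident_steps,disperser_steps simulated steps per bear-year
#' @param resident_truth,disperser_truth generative kernels
#' @param landscape a \code{\link{landscape_config}} (its seed is derived
#'   from the master seed)
#' @param ratio available-to-used ratio (both scales)
#' @param buffer_m MCP buffer radius, meters
#' @param max_dop DOP threshold
#' @param min_day_coverage resident active-period day coverage
#' @param ci_mult CI multiplier
#' @param n_candidates candidate endpoints per simulated step
#' @param rate_grid_m distance grid for rate and RSS curves, meters
#' @param segment run HMM segmentation on disperser tracks (slower); when
#'   FALSE the known simulation window is used directly
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(seed = 1L,
                            n_residents = 20L, n_dispersers = 15L,
                            resident_steps = 118L * 24L,
                            disperser_steps = 43L * 24L,
                            resident_truth = default_truth("resident"),
                            disperser_truth = default_truth("disperser"),
                            landscape = landscape_config(extent_m = 20000),
                            ratio = 20L, buffer_m = 18000,
                            max_dop = 10, min_day_coverage = 0.70,
                            ci_mult = 1.96, n_candidates = 200L,
                            rate_grid_m = seq(0, 500, by = 25),
                            segment = FALSE, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

simulate_bear_years <- function(cfg, stack) {
  ext <- stack$nx * stack$res
  tracks <- list()
  meta <- list()
  for (ls in c("resident", "disperser")) {
    n <- if (ls == "resident") cfg$n_residents else cfg$n_dispersers
    nst <- if (ls == "resident") cfg$resident_steps else cfg$disperser_steps
    truth <- if (ls == "resident") cfg$resident_truth else cfg$disperser_truth
    t0 <- if (ls == "resident") as.POSIXct("2015-04-25 00:00:00", tz = "UTC")
          else as.POSIXct("2015-05-15 00:00:00", tz = "UTC")
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", ls, i)
      sseed <- derive_seed(cfg$seed, paste0("sim_", id))
      start <- with_seed(sseed, stats::runif(2, 0.25 * ext, 0.75 * ext))
      sim <- simulate_issa_track(stack, truth, n_steps = nst, start = start,
                                 seed = sseed + 1L, bear_year_id = id, t0 = t0,
                                 n_candidates = cfg$n_candidates)
      art <- inject_artifacts(sim$track,
                              bed_cluster_spec = list(n_clusters = max(1L, nst %/% 25L),
                                                      n_fixes = 6L, radius_m = 10),
                              dop_spec = list(frac_high = 0.03),
                              gap_spec = list(n_gaps = 3L, gap_len = 1L),
                              seed = sseed + 2L)
      tracks[[id]] <- art$track
      meta[[id]] <- list(life_stage = ls, truth = truth,
                         window = range(sim$track$t), artifact_log = art$log)
    }
  }
  list(tracks = tracks, meta = meta)
}

#' Run the full synthetic study end to end
#'
#' simulate -> preprocess -> (segment) -> steps & covariates -> RSF & iSSA
#' candidate fits per bear-year -> AIC selection summaries -> IVW population
#' estimates -> movement-rate and RSS curves. Identical config and seed give
#' identical outputs. When \code{config$out_dir} is set, selection
#' summaries, population tables and curves are written as CSV together with
#' a JSON manifest of seeds and stage record counts.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return list with elements \code{landscape}, \code{tracks} (cleaned),
#'   \code{kernel} (pooled tentative gamma), \code{fits_aic} (per bear-year x
#'   model x scale AIC table), \code{selection} (per life stage x scale
#'   summaries), \code{population} (per life stage x scale Table-4-shaped
#'   tables), \code{rate_curves}, \code{rss_curves}, \code{manifest}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  lcfg <- cfg$landscape
  lcfg$seed <- derive_seed(cfg$seed, "landscape")
  stack <- generate_landscape(lcfg)

  sim <- simulate_bear_years(cfg, stack)

  # --- preprocess -----------------------------------------------------------
  clean <- list(); life_stage <- character(0)
  for (id in names(sim$tracks)) {
    ls <- sim$meta[[id]]$life_stage
    win <- if (ls == "disperser") {
      if (cfg$segment) {
        st <- movement_steps(sim$tracks[[id]])
        hf <- select_hmm(st, seed = derive_seed(cfg$seed, paste0("hmm_", id)))
        dw <- delineate_dispersal(hf$decoded_states, st$t, fit = hf)
        if (is.null(dw)) sim$meta[[id]]$window else c(dw$onset, dw$end)
      } else sim$meta[[id]]$window
    } else NULL
    tr <- preprocess_track(sim$tracks[[id]], stack = stack, life_stage = ls,
                           dispersal_window = win, max_dop = cfg$max_dop,
                           min_day_coverage = cfg$min_day_coverage)
    if (is.null(tr)) next
    clean[[id]] <- tr
    life_stage[id] <- ls
  }

  # --- steps and pooled tentative gamma ------------------------------------
  steps <- lapply(clean, build_steps)
  kernel <- fit_tentative_gamma(unlist(lapply(steps, `[[`, "sl")))

  # --- local scale: available steps and life-stage standardization ---------
  step_sets <- list()
  for (id in names(clean)) {
    step_sets[[id]] <- generate_available_steps(
      steps[[id]], kernel, ratio = cfg$ratio,
      seed = derive_seed(cfg$seed, paste0("avail_", id)), stack = stack)
  }
  covs <- c("bog", "clearcut", "tri", "log_dist_water", "log_dist_forestry",
            "log_dist_public", "log_dist_building")
  std_issa <- list(); issa_data <- list()
  for (ls in unique(life_stage)) {
    ids <- names(clean)[life_stage == ls]
    pooled <- do.call(rbind, lapply(ids, function(id)
      extract_covariates(stack, step_sets[[id]]$x1, step_sets[[id]]$y1)))
    std_issa[[ls]] <- standardize_table(pooled, covs)
    for (id in ids)
      issa_data[[id]] <- step_covariates(step_sets[[id]], stack, std = std_issa[[ls]])$data
  }

  # --- landscape scale: availability region and RSF data -------------------
  region <- build_availability(clean, buffer_m = cfg$buffer_m)
  rsf_raw <- list()
  for (id in names(clean)) {
    tr <- clean[[id]]
    used <- tr[!tr$bed_site, , drop = FALSE]
    av <- sample_available(region, nrow(used), ratio = cfg$ratio,
                           seed = derive_seed(cfg$seed, paste0("rsfav_", id)),
                           stack = stack)
    cu <- extract_covariates(stack, used$x, used$y)
    ca <- extract_covariates(stack, av$x, av$y)
    rsf_raw[[id]] <- rbind(cbind(case = 1L, cu), cbind(case = 0L, ca))
  }
  std_rsf <- list(); rsf_data <- list()
  for (ls in unique(life_stage)) {
    ids <- names(clean)[life_stage == ls]
    std_rsf[[ls]] <- standardize_table(do.call(rbind, lapply(ids, function(id)
      rsf_raw[[id]][, covs])), covs)
    for (id in ids) {
      d <- rsf_raw[[id]]
      d[, covs] <- apply_standardization(d[, covs], std_rsf[[ls]])
      rsf_data[[id]] <- d
    }
  }

  # --- candidate fits -------------------------------------------------------
  issa_models <- candidate_models("issa")
  rsf_models <- candidate_models("rsf")
  fits_aic <- list()
  full_fits <- list(issa = list(), rsf = list())
  for (id in names(clean)) {
    for (mn in names(issa_models)) {
      f <- tryCatch(
        fit_clogit(issa_data[[id]], issa_models[[mn]], model_name = mn,
                   bear_year_id = id),
        error = function(e) {
          warning("iSSA fit failed for ", id, " / ", mn, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(f)) next
      fits_aic[[length(fits_aic) + 1]] <- data.frame(
        bear_year_id = id, life_stage = life_stage[id], scale = "local",
        model_name = mn, aic = f$aic)
      if (mn == "full") full_fits$issa[[id]] <- f
    }
    for (mn in names(rsf_models)) {
      f <- tryCatch(
        fit_rsf(rsf_data[[id]], rsf_models[[mn]], model_name = mn,
                bear_year_id = id),
        error = function(e) {
          warning("RSF fit failed for ", id, " / ", mn, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(f)) next
      fits_aic[[length(fits_aic) + 1]] <- data.frame(
        bear_year_id = id, life_stage = life_stage[id], scale = "landscape",
        model_name = mn, aic = f$aic)
      if (mn == "full") full_fits$rsf[[id]] <- f
    }
  }
  fits_aic <- do.call(rbind, fits_aic)

  # --- selection summaries and population estimates ------------------------
  selection <- list(); population <- list()
  for (ls in unique(life_stage)) {
    for (sc in c("landscape", "local")) {
      key <- paste(ls, sc, sep = "_")
      sub <- fits_aic[fits_aic$life_stage == ls & fits_aic$scale == sc, ]
      selection[[key]] <- suppressWarnings(summarize_selection(sub))
      ids <- intersect(names(clean)[life_stage == ls],
                       names(if (sc == "local") full_fits$issa else full_fits$rsf))
      flist <- if (sc == "local") full_fits$issa[ids] else full_fits$rsf[ids]
      avail <- if (sc == "local") {
        do.call(rbind, lapply(ids, function(id) {
          d <- issa_data[[id]][issa_data[[id]]$case == 0, ]
          as.data.frame(as.list(colMeans(d[, paste0(covs, "_end")])),
                        col.names = covs)
        }))
      } else {
        do.call(rbind, lapply(ids, function(id) {
          d <- rsf_data[[id]][rsf_data[[id]]$case == 0, ]
          as.data.frame(as.list(colMeans(d[, covs])))
        }))
      }
      population[[key]] <- if (length(flist) >= 3) {
        population_estimates(flist, availability = avail)
      } else {
        warning("fewer than 3 usable full-model fits for ", key,
                "; population estimates skipped", call. = FALSE)
        NULL
      }
    }
  }

  # --- post-estimation: rate and RSS curves --------------------------------
  rate_curves <- list(); rss_curves <- list()
  for (ls in unique(life_stage)) {
    ids <- intersect(names(clean)[life_stage == ls], names(full_fits$issa))
    models <- lapply(ids, function(id) {
      st <- steps[[id]]
      sm <- list(clearcut = mean(extract_covariates(stack, st$x0, st$y0)$clearcut),
                 log_dist_forestry = mean(log(extract_covariates(stack, st$x0, st$y0)$dist_forestry + 1)),
                 log_dist_public = mean(log(extract_covariates(stack, st$x0, st$y0)$dist_public + 1)),
                 log_dist_building = mean(log(extract_covariates(stack, st$x0, st$y0)$dist_building + 1)))
      list(coefs = stats::coef(full_fits$issa[[id]]), kernel = kernel,
           std = std_issa[[ls]], start_means = sm)
    })
    for (focal in c("log_dist_forestry", "log_dist_public", "log_dist_building")) {
      rc <- rate_curve(models, focal, grid_m = cfg$rate_grid_m)
      rc$life_stage <- ls; rc$focal <- focal
      rate_curves[[paste(ls, focal, sep = "_")]] <- rc
    }
    pe <- population[[paste(ls, "local", sep = "_")]]
    for (cov in c("log_dist_forestry", "log_dist_public", "log_dist_building")) {
      b <- pe$estimate[pe$coefficient == paste0(cov, "_end")]
      rs <- rss_distance_curve(b, cov, std_issa[[ls]],
                               mean_sl = kernel$shape * kernel$scale,
                               grid_m = cfg$rate_grid_m)
      rs$life_stage <- ls; rs$covariate <- cov
      rss_curves[[paste(ls, cov, sep = "_")]] <- rs
    }
  }

  manifest <- list(seed = cfg$seed, n_bear_years = length(clean),
                   life_stage = as.list(table(life_stage)),
                   kernel = unclass(kernel),
                   n_fixes = vapply(clean, nrow, 0L))
  result <- list(landscape = stack, tracks = clean, life_stage = life_stage,
                 kernel = kernel, fits_aic = fits_aic, selection = selection,
                 population = population, full_fits = full_fits,
                 std_issa = std_issa, std_rsf = std_rsf,
                 rate_curves = do.call(rbind, rate_curves),
                 rss_curves = do.call(rbind, rss_curves),
                 manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$fits_aic, file.path(dir, "fits_aic.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(result$selection), function(k)
    cbind(set = k, as.data.frame(result$selection[[k]]))))
  utils::write.csv(sel, file.path(dir, "selection_summary.csv"), row.names = FALSE)
  pop <- do.call(rbind, lapply(names(result$population), function(k)
    cbind(set = k, result$population[[k]])))
  utils::write.csv(pop, file.path(dir, "population_estimates.csv"), row.names = FALSE)
  utils::write.csv(result$rate_curves, file.path(dir, "rate_curves.csv"), row.names = FALSE)
  utils::write.csv(result$rss_curves, file.path(dir, "rss_curves.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
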