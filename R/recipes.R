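#' Figure-style experiment recipes
#'
#' Bundled end-to-end experiments over the calibrated profiles, each
#' writing CSV/JSON outputs plus a run manifest to `out_dir`:
#'
#' * `"dynamic-L4"`: mean dominance duration versus frame interval for the
#'   two-pool memory profile, including the no-alternation check beyond the
#'   alternation boundary.
#' * `"habituation"`: dominance duration by percept epoch from rest, for
#'   the local-fatigue and nonlocal-fatigue profiles (opposite first-epoch
#'   behaviour).
#' * `"bifurcation"`: fixed-point branches and regime labels of the
#'   two-pool circuit across static drive (smoothed gain).
#' * `"memory-region"`: alternation map over frame intervals with the
#'   boundary estimate.
#' * `"survival-recovery"`: parameter-recovery check of the Cox stage on
#'   synthetic report datasets with known effect sizes.
#' * `"spiking"`: dynamic L4 and rested habituation in the spiking circuit
#'   across seeds.
#'
#' @param name recipe name (unknown names list the available recipes).
#' @param out_dir output directory.
#' @param seed integer seed fanned out to the recipe's random components.
#' @return Invisibly, the recipe's summary list (also written as JSON).
#' @export
run_recipe <- function(name, out_dir, seed = 1) {
  known <- c("dynamic-L4", "habituation", "bifurcation", "memory-region",
             "survival-recovery", "spiking")
  if (!name %in% known)
    stop("unknown recipe '", name, "'; available: ",
         paste(known, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fun <- switch(name,
    "dynamic-L4" = recipe_dynamic_L4,
    "habituation" = recipe_habituation,
    "bifurcation" = recipe_bifurcation,
    "memory-region" = recipe_memory_region,
    "survival-recovery" = recipe_survival_recovery,
    "spiking" = recipe_spiking)
  res <- fun(out_dir, seed)
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(res$summary, f_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_manifest(out_dir, kind = paste0("recipe:", name),
                 params = res$params, seed = seed,
                 files = c(res$files, f_sum))
  invisible(res$summary)
}

recipe_dynamic_L4 <- function(out_dir, seed) {
  pr <- rivalry_profile("two-pool-memory")
  grid <- c(pr$L4_grid_ms, pr$no_alt_T_frame_ms)
  sw <- sweep_dynamic_L4(pr$circuit, grid,
                         pulse_spec(pr$S_on, width_ms = pr$pulse_width_ms),
                         background_spec("fixed", S_off = pr$S_off),
                         horizon_frames = 150,
                         state0 = kicked_state(pr$circuit, pr$kick_pool,
                                               pr$kick_eps))
  f <- file.path(out_dir, "dynamic_L4.csv")
  utils::write.csv(sw, f, row.names = FALSE)
  list(summary = list(
    profile = pr$name, T_frame_ms = sw$T_frame_ms, mean_TD = sw$mean_TD,
    no_alternation = sw$no_alternation,
    monotone = !is.unsorted(sw$mean_TD[!sw$no_alternation])),
    params = pr[c("name", "S_on", "S_off", "pulse_width_ms", "L4_grid_ms")],
    files = f)
}

recipe_habituation <- function(out_dir, seed) {
  out <- list(); curves <- list()
  for (nm in c("two-pool-memory", "two-pool-nonlocal")) {
    pr <- rivalry_profile(nm)
    proto <- profile_protocol(pr, n_frames = 120)
    tr <- simulate(pr$circuit, protocol = proto,
                   state0 = kicked_state(pr$circuit, pr$kick_pool,
                                         pr$kick_eps))
    hc <- habituation_curve(dominance_records(dominant_labels(tr)))
    curves[[nm]] <- cbind(profile = nm, hc)
    out[[nm]] <- list(epoch_TD = hc$T_D,
                      first_longer = hc$T_D[1] > hc$T_D[2])
  }
  f <- file.path(out_dir, "habituation.csv")
  utils::write.csv(do.call(rbind, curves), f, row.names = FALSE)
  list(summary = out,
       params = list(T_frame_ms = 105, n_frames = 120), files = f)
}

recipe_bifurcation <- function(out_dir, seed) {
  pr <- rivalry_profile("two-pool-memory")
  circ <- pr$circuit
  circ$gain <- gain_function("smoothed", smoothing_scale = 1e-3)
  grid <- c(-0.5, -0.1, 0.05, 0.2, 0.5, 1, 2, 4, 6, 7, 8, 9, 10, 12)
  scan <- bifurcation_scan(circ, grid, cycle_window_tau_a = 30)
  f <- file.path(out_dir, "regime_scan.csv")
  utils::write.csv(as.data.frame(scan), f, row.names = FALSE)
  list(summary = list(S = scan$regimes$S, regime = scan$regimes$regime),
       params = list(profile = pr$name, gain = "smoothed(1e-3)",
                     S_grid = grid),
       files = f)
}

recipe_memory_region <- function(out_dir, seed) {
  pr <- rivalry_profile("two-pool-memory")
  grid <- c(pr$L4_grid_ms, 650, pr$no_alt_T_frame_ms, 800)
  mr <- memory_region(pr$circuit, pr$S_on, grid,
                      pulse_width_ms = pr$pulse_width_ms, S_off = pr$S_off)
  f <- file.path(out_dir, "memory_region.csv")
  utils::write.csv(mr, f, row.names = FALSE)
  list(summary = list(T_frame_ms = mr$T_frame_ms,
                      alternates = mr$alternates,
                      boundary_ms = attr(mr, "boundary_ms")),
       params = pr[c("name", "S_on", "S_off", "pulse_width_ms")],
       files = f)
}

recipe_survival_recovery <- function(out_dir, seed, n_rep = 20) {
  beta_T <- log(0.996); beta_E <- log(1.024)
  hit_T <- hit_E <- logical(n_rep)
  rows <- list()
  # one effect at a time: the single-covariate fit is only a consistent
  # estimator of the coefficient it was generated with (hazard ratios are
  # not collapsible over omitted covariates)
  for (r in seq_len(n_rep)) {
    dsT <- synth_reports(n_subjects = 8,
                         block_duration_ms = 60000 * c(2, 2, 2, 2),
                         beta_T_frame = beta_T, beta_epoch = 0,
                         frailty_var = 0.1, epoch_cap = Inf,
                         seed = seed * 10000 + r)
    dsE <- synth_reports(n_subjects = 8,
                         block_duration_ms = 60000 * c(2, 2, 2, 2),
                         beta_T_frame = 0, beta_epoch = beta_E,
                         frailty_var = 0.1, epoch_cap = Inf,
                         seed = seed * 10000 + 5000 + r)
    ft <- fit_cox_mixed(screen_subjects(records_from_reports(dsT)),
                        fixed = "T_frame")
    fe <- fit_cox_mixed(screen_subjects(records_from_reports(dsE)),
                        fixed = "epoch")
    hit_T[r] <- abs(ft$coef - beta_T) <= 2 * ft$se
    hit_E[r] <- abs(fe$coef - beta_E) <= 2 * fe$se
    rows[[r]] <- data.frame(rep = r, coef_T = ft$coef, se_T = ft$se,
                            coef_E = fe$coef, se_E = fe$se,
                            hit_T = hit_T[r], hit_E = hit_E[r])
  }
  f <- file.path(out_dir, "survival_recovery.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
  list(summary = list(
    true_coef_T_frame = beta_T, true_coef_epoch = beta_E,
    recovery_rate_T_frame = mean(hit_T), recovery_rate_epoch = mean(hit_E),
    n_replicates = n_rep),
    params = list(n_subjects = 8, frailty_var = 0.1, n_rep = n_rep),
    files = f)
}

recipe_spiking <- function(out_dir, seed, n_seeds = 5) {
  pr <- rivalry_profile("spiking")
  grid <- pr$L4_grid_ms
  rows <- list()
  for (s in seq_len(n_seeds)) {
    for (Tf in grid) {
      proto <- stimulus_protocol(frame_sequence(Tf, 150),
                                 pulse_spec(pr$S_on,
                                            width_ms = pr$pulse_width_ms),
                                 background_spec("zero"))
      rec <- rates_to_records(simulate_spiking(pr$spiking, proto,
                                               seed = seed * 1000 + s))
      unc <- rec[!rec$censored, ]
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, T_frame_ms = Tf,
        # no alternation within the horizon counts as unbounded dominance
        mean_TD = if (nrow(unc)) mean(unc$T_D) else Inf,
        first_TD = if (nrow(unc)) unc$T_D[1] else NA,
        second_TD = if (nrow(unc) > 1) unc$T_D[2] else NA)
    }
  }
  df <- do.call(rbind, rows)
  f <- file.path(out_dir, "spiking_L4.csv")
  utils::write.csv(df, f, row.names = FALSE)
  mono <- vapply(split(df, df$seed), function(d)
    !is.unsorted(d$mean_TD[order(d$T_frame_ms)]), logical(1))
  hab <- with(df, first_TD > second_TD)
  list(summary = list(T_frame_ms = grid, n_seeds = n_seeds,
                      monotone_fraction = mean(mono),
                      first_epoch_longer_fraction = mean(hab, na.rm = TRUE)),
       params = list(neurons_per_pool = pr$spiking$neurons_per_pool,
                     n_seeds = n_seeds),
       files = f)
}
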