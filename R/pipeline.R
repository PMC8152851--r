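#' Run the microstimulation pipeline end to end
#'
#' For each simulated session: build the daily stimulus design (gloss
#' ladder, fresh seeded shape set, 210-condition grid), simulate one trial
#' per condition from the behavioral ground truth (the per-session
#' stimulation offset shift comes from recycling `config$delta_b_stim`
#' over sessions), aggregate choices by stimulation condition, fit both
#' psychometric functions, screen fit quality, run the permutation test for
#' Δa and Δb, and classify the shift direction. Since the generator's truth
#' is known, the summary includes a confusion matrix of flagged sessions
#' against sessions with a true nonzero stimulation effect.
#'
#' @param config a [gloss_config()].
#' @return list of class `microstim_run` with `sessions` (one row per
#'   session: fits, Δa/Δb, p-values, significance, direction, exclusion
#'   status, true effect, provenance) and `summary` (counts, sensitivity,
#'   specificity).
#' @export
run_microstim_pipeline <- function(config) {
  validate_config(config)
  n <- config$n_sessions
  hash <- config_hash(config)
  empty <- data.frame(
    session = integer(), seed = integer(),
    a_stim = numeric(), b_stim = numeric(),
    a_ctrl = numeric(), b_ctrl = numeric(),
    excluded = logical(), exclusion_reason = character(),
    delta_a = numeric(), delta_b = numeric(),
    p_a = numeric(), p_b = numeric(),
    significant_a = logical(), significant_b = logical(),
    direction = character(), true_delta_b = numeric(),
    config_hash = character(), stringsAsFactors = FALSE)
  if (n == 0)
    return(structure(list(sessions = empty,
                          summary = list(n_sessions = 0L, n_excluded = 0L,
                                         n_significant_b = 0L)),
                     class = "microstim_run"))

  ladder <- build_gloss_ladder(config$c_min, config$c_max, config$n_levels,
                               config$cd_ratio, config$d_anchor)
  seeds <- seed_schedule(config$seed, n)
  effects <- rep_len(config$delta_b_stim, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    shapes <- generate_shape_set(config$seed + i, config$n_shapes,
                                 config$basis_order)
    grid <- build_condition_grid(ladder, shapes, config$illuminations,
                                 include_stimulation_factor = TRUE)
    truth <- config_truth(config, delta_b_stim = effects[i])
    sub_seeds <- seed_schedule(seeds[i], 2L)
    trials <- simulate_session_choices(truth, grid, seed = sub_seeds[1L],
                                       session_id = sprintf("session%03d", i))
    tab <- aggregate_choice_proportions(trials, "stimulation",
                                        levels = ladder$levels$level)
    fit_s <- fit_logistic(tab[tab$group == "stim", ])
    fit_c <- fit_logistic(tab[tab$group == "no_stim", ])
    q_s <- evaluate_fit_quality(fit_s, config$exclusion_rms)
    q_c <- evaluate_fit_quality(fit_c, config$exclusion_rms)
    excluded <- !(q_s$keep && q_c$keep)
    reason <- if (!q_s$keep) q_s$reason else if (!q_c$keep) q_c$reason else "ok"

    if (excluded) {
      pr <- list(delta_a = NA_real_, delta_b = NA_real_, p_a = NA_real_,
                 p_b = NA_real_, significant_a = NA, significant_b = NA)
      direction <- NA_character_
    } else {
      pr <- permutation_test(trials[trials$stimulation, ],
                             trials[!trials$stimulation, ],
                             n_perm = config$n_perm, seed = sub_seeds[2L],
                             tail_criterion = config$tail_criterion)
      direction <- classify_shift_direction(pr)
    }
    rows[[i]] <- data.frame(
      session = i, seed = seeds[i],
      a_stim = fit_s$a, b_stim = fit_s$b,
      a_ctrl = fit_c$a, b_ctrl = fit_c$b,
      excluded = excluded, exclusion_reason = reason,
      delta_a = pr$delta_a, delta_b = pr$delta_b,
      p_a = pr$p_a, p_b = pr$p_b,
      significant_a = pr$significant_a, significant_b = pr$significant_b,
      direction = direction, true_delta_b = effects[i],
      config_hash = hash, stringsAsFactors = FALSE)
  }
  sessions <- do.call(rbind, rows)

  tested <- sessions[!sessions$excluded, ]
  truth_pos <- tested$true_delta_b != 0
  flagged <- tested$significant_b
  summary <- list(
    n_sessions = n,
    n_excluded = sum(sessions$excluded),
    n_significant_b = sum(flagged, na.rm = TRUE),
    n_true_effect = sum(truth_pos),
    tp = sum(flagged & truth_pos), fp = sum(flagged & !truth_pos),
    fn = sum(!flagged & truth_pos), tn = sum(!flagged & !truth_pos),
    sensitivity = if (any(truth_pos)) mean(flagged[truth_pos]) else NA_real_,
    specificity = if (any(!truth_pos)) mean(!flagged[!truth_pos]) else NA_real_,
    config_hash = hash, seed = config$seed
  )
  structure(list(sessions = sessions, summary = summary),
            class = "microstim_run")
}

#' Run the muscimol inactivation pipeline end to end
#'
#' Simulates `config$n_injections` successive injections at one site: for
#' each, a pre-injection session and sessions at every post-injection time
#' point on the 105-condition no-stimulation grid, followed by the
#' slope-change permutation test at each time point. Repeated injections
#' attenuate the simulated deficit geometrically. Reports the per-injection
#' time course, a recovery check at the last time point, and the
#' repeated-injection attenuation summary.
#'
#' @param config a [gloss_config()].
#' @return list of class `muscimol_run` with `timecourse` (rows: injection
#'   x time point), `injections` (18-h effect per injection + trend), and
#'   `recovery` (last-time-point significance per injection).
#' @export
run_muscimol_pipeline <- function(config) {
  validate_config(config)
  hash <- config_hash(config)
  ladder <- build_gloss_ladder(config$c_min, config$c_max, config$n_levels,
                               config$cd_ratio, config$d_anchor)
  truth <- config_truth(config)
  n_inj <- config$n_injections
  seeds <- seed_schedule(config$seed + 1L, n_inj)

  tcs <- vector("list", n_inj)
  rows <- vector("list", n_inj)
  for (k in seq_len(n_inj)) {
    shapes <- generate_shape_set(config$seed + k, config$n_shapes,
                                 config$basis_order)
    grid <- build_condition_grid(ladder, shapes, config$illuminations,
                                 include_stimulation_factor = FALSE)
    sub <- seed_schedule(seeds[k], length(config$timepoints) + 1L)
    series <- simulate_muscimol_series(
      truth, grid, seeds = sub[-1L], timepoints = config$timepoints,
      injection_index = k - 1L, site_id = sprintf("site_seed%d", config$seed))
    tc <- slope_timecourse(series, n_perm = config$n_perm, seed = sub[1L],
                           tail_criterion = config$tail_criterion)
    tc$injection <- k
    tc$config_hash <- hash
    tcs[[k]] <- tc
    rows[[k]] <- as.data.frame(tc)
  }
  timecourse <- do.call(rbind, rows)
  injections <- repeated_injection_summary(tcs, at_timepoint_h = 18)
  last_tp <- max(config$timepoints)
  recovery <- data.frame(
    injection = seq_len(n_inj),
    timepoint_h = last_tp,
    significant = vapply(tcs, function(tc)
      tc$significant[match(last_tp, tc$timepoint_h)], NA),
    config_hash = hash)
  structure(list(timecourse = timecourse, injections = injections,
                 recovery = recovery,
                 summary = list(trend = attr(injections, "trend"),
                                config_hash = hash, seed = config$seed)),
            class = "muscimol_run")
}
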