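#' Ground truth for a simulated multiunit site
#'
#' Describes the latent response model of one multiunit site: a Poisson
#' baseline rate, a per-shape response gain, a monotone gloss tuning
#' function on [0, 1], a preference sign (+1 responds more to glossier
#' stimuli, -1 to more matte stimuli), and a confound mode controlling
#' whether shuffled-image responses track gloss level. `confound_mode =
#' "luminance"` emulates a site driven by mean luminance rather than gloss:
#' its shuffled-image responses follow the same level dependence as its
#' object responses, so the shuffled-image control should reject it.
#'
#' @param unit_id character id.
#' @param base_rate baseline firing rate in spikes/s (default 40, the
#'   multiunit thresholding criterion the recordings emulate).
#' @param gains named numeric vector of per-shape response gains (spikes/s);
#'   names are shape ids.
#' @param tuning_fn monotone function mapping gloss level 1..n to [0, 1];
#'   default linear over 7 levels.
#' @param sign +1 (prefers glossy) or -1 (prefers matte).
#' @param confound_mode `"none"` or `"luminance"`.
#' @param n_levels number of gloss levels the tuning is defined over.
#' @return an object of class `unit_truth`.
#' @export
unit_truth <- function(unit_id = "unit1", base_rate = 40, gains,
                       tuning_fn = function(level) (level - 1) / 6,
                       sign = 1L, confound_mode = c("none", "luminance"),
                       n_levels = 7L) {
  confound_mode <- match.arg(confound_mode)
  gp_check(is.character(unit_id) && length(unit_id) == 1L, "unit_id must be a string")
  gp_check(is.numeric(base_rate) && length(base_rate) == 1L && base_rate > 0,
           "base_rate must be a single positive number")
  gp_check(is.numeric(gains) && length(gains) >= 1 && !is.null(names(gains)) &&
             all(nzchar(names(gains))) && all(is.finite(gains)),
           "gains must be a named finite numeric vector (names = shape ids)")
  gp_check(is.function(tuning_fn), "tuning_fn must be a function")
  gp_check(sign %in% c(-1, 1), "sign must be +1 or -1")
  gp_check(is_count(n_levels) && n_levels >= 2, "n_levels must be an integer >= 2")
  tv <- tuning_fn(seq_len(n_levels))
  gp_check(all(is.finite(tv)) && all(tv >= 0) && all(tv <= 1),
           "tuning_fn must map levels into [0, 1]")
  gp_check(all(diff(tv) >= 0), "tuning_fn must be monotone non-decreasing in level")
  structure(list(unit_id = unit_id, base_rate = base_rate, gains = gains,
                 tuning_fn = tuning_fn, sign = as.integer(sign),
                 confound_mode = confound_mode, n_levels = as.integer(n_levels)),
            class = "unit_truth")
}

#' Simulate spike-count records for one unit
#'
#' Draws Poisson spike counts for each stimulus in a selectivity set over
#' `n_repeats` repetitions. The response window is 300 ms starting 50 ms
#' after stimulus onset and the baseline window is the 300 ms before onset;
#' counts are Poisson with mean `rate x 0.3 s`. Object-image rates are
#' `base_rate + gain[shape] * tuning(level)` for glossy-preferring units
#' (the tuning is reversed in level for matte-preferring units).
#' Shuffled-image rates are flat at `base_rate` when `confound_mode =
#' "none"` and track the level tuning when `confound_mode = "luminance"`.
#'
#' @param unit a [unit_truth()] object.
#' @param stimulus_set a [build_selectivity_stimulus_set()] data frame (or
#'   any data frame with `gloss_level`, `shape_id`, `shuffled`).
#' @param n_repeats repetitions per stimulus; the downstream analysis
#'   requires at least 5.
#' @param seed integer seed.
#' @param response_window_s,baseline_window_s window durations in seconds.
#' @return a data frame of class `spike_trials` with one row per
#'   stimulus x repeat: `unit_id`, `shape_id`, `shuffled`, `gloss_level`,
#'   `repeat_index`, `baseline_count`, `response_count`. Window durations
#'   are carried in attributes `response_window_s` / `baseline_window_s`,
#'   and the latent truth in attribute `manifest`.
#' @export
simulate_unit_responses <- function(unit, stimulus_set, n_repeats = 10L, seed,
                                    response_window_s = 0.3,
                                    baseline_window_s = 0.3) {
  gp_check(inherits(unit, "unit_truth"), "unit must be a unit_truth object")
  gp_check(is.data.frame(stimulus_set) &&
             all(c("gloss_level", "shape_id", "shuffled") %in% names(stimulus_set)),
           "stimulus_set must have gloss_level, shape_id and shuffled columns")
  gp_check(is_count(n_repeats) && n_repeats >= 5,
           "n_repeats must be an integer >= 5 (analysis minimum)")
  gp_check(response_window_s > 0 && baseline_window_s > 0,
           "window durations must be positive")

  lv <- stimulus_set$gloss_level
  gp_check(all(lv >= 1 & lv <= unit$n_levels), "gloss levels outside the unit's tuning range")
  tl <- if (unit$sign > 0) unit$tuning_fn(lv) else unit$tuning_fn(unit$n_levels + 1 - lv)
  gain <- unit$gains[stimulus_set$shape_id]
  gain[is.na(gain)] <- 0
  mu <- unit$base_rate + unname(gain) * tl
  flat_shuffled <- stimulus_set$shuffled & unit$confound_mode == "none"
  mu[flat_shuffled] <- unit$base_rate
  gp_check(all(mu >= 0), "negative mean rate after gain composition")

  n_stim <- nrow(stimulus_set)
  out <- with_rng(seed, {
    data.frame(
      unit_id = unit$unit_id,
      shape_id = rep(stimulus_set$shape_id, each = n_repeats),
      shuffled = rep(stimulus_set$shuffled, each = n_repeats),
      gloss_level = rep(lv, each = n_repeats),
      repeat_index = rep(seq_len(n_repeats), times = n_stim),
      baseline_count = rpois(n_stim * n_repeats,
                             unit$base_rate * baseline_window_s),
      response_count = rpois(n_stim * n_repeats,
                             rep(mu, each = n_repeats) * response_window_s),
      stringsAsFactors = FALSE
    )
  })
  structure(out,
            response_window_s = response_window_s,
            baseline_window_s = baseline_window_s,
            manifest = list(unit = unclass(unit), n_repeats = n_repeats,
                            seed = seed, mean_rates = mu),
            class = c("spike_trials", "data.frame"))
}

#' Behavioral ground truth for the gloss discrimination task
#'
#' Latent parameters of the choice generator. Choices follow the logistic
#' psychometric function `P(glossier) = 1 / (1 + exp(-a_eff (x - b_eff)))`
#' in gloss-level units `x`. Microstimulation perturbs the curve by an
#' additive offset shift `delta_b_stim` (negative values bias judgments
#' toward "glossier") and a multiplicative slope factor `stim_slope_factor`.
#' Muscimol inactivation is modeled as a pure slope multiplier given by
#' `muscimol_profile` at each post-injection time point (hours); repeated
#' injections attenuate the deficit geometrically:
#' `multiplier(t, k) = 1 - (1 - profile[t]) * injection_attenuation^k`
#' for injection index `k` (0 = first injection).
#'
#' @param a slope of the logistic (per gloss-level unit); must be > 0.
#' @param b offset, the gloss level of the 50% point.
#' @param delta_b_stim stimulation-induced additive offset shift.
#' @param stim_slope_factor stimulation-induced multiplicative slope change.
#' @param muscimol_profile named numeric vector of slope multipliers in
#'   (0, 1], keyed by time point in hours; `"0"` is the pre-injection epoch
#'   and must equal 1. Default: 0.8 at 0.5 h, minimum 0.4 at 18 h, full
#'   recovery (1.0) at 42 h.
#' @param injection_attenuation per-repeat multiplier in (0, 1] on the
#'   muscimol deficit.
#' @return an object of class `behavior_truth`.
#' @export
behavior_truth <- function(a = 1, b = 4, delta_b_stim = 0, stim_slope_factor = 1,
                           muscimol_profile = c("0" = 1, "0.5" = 0.8,
                                                "18" = 0.4, "42" = 1.0),
                           injection_attenuation = 1) {
  gp_check(is.numeric(a) && length(a) == 1L && is.finite(a) && a > 0,
           "slope a must be a single positive number")
  gp_check(is.numeric(b) && length(b) == 1L && is.finite(b), "offset b must be finite")
  gp_check(is.numeric(delta_b_stim) && length(delta_b_stim) == 1L &&
             is.finite(delta_b_stim), "delta_b_stim must be finite")
  gp_check(is.numeric(stim_slope_factor) && length(stim_slope_factor) == 1L &&
             stim_slope_factor > 0, "stim_slope_factor must be positive")
  gp_check(is.numeric(muscimol_profile) && !is.null(names(muscimol_profile)) &&
             all(muscimol_profile > 0) && all(muscimol_profile <= 1),
           "muscimol_profile must be a named vector of multipliers in (0, 1]")
  gp_check(!("0" %in% names(muscimol_profile)) || muscimol_profile[["0"]] == 1,
           "the pre-injection profile entry (time 0) must be 1")
  gp_check(injection_attenuation > 0 && injection_attenuation <= 1,
           "injection_attenuation must be in (0, 1]")
  structure(list(a = a, b = b, delta_b_stim = delta_b_stim,
                 stim_slope_factor = stim_slope_factor,
                 muscimol_profile = muscimol_profile,
                 injection_attenuation = injection_attenuation),
            class = "behavior_truth")
}

#' @noRd
muscimol_multiplier <- function(truth, timepoint_h, injection_index) {
  key <- tp_key(timepoint_h)
  gp_check(key %in% names(truth$muscimol_profile),
           sprintf("muscimol_profile has no entry for time point %s h", key))
  m <- truth$muscimol_profile[[key]]
  1 - (1 - m) * truth$injection_attenuation^injection_index
}

#' Simulate one session of gloss-choice trials
#'
#' Runs every condition of the grid once (the canonical session design) and
#' draws a Bernoulli "glossier" choice from the logistic psychometric model
#' in [behavior_truth()]. For stimulation trials the effective parameters
#' are `a * stim_slope_factor` and `b + delta_b_stim`; for muscimol epochs
#' (`timepoint_h` given) the slope is multiplied by the attenuated profile
#' value. Trials at the middle gloss level (where test equals reference)
#' are rewarded at random; all other trials are rewarded when the choice
#' matches the true ordering. Choices at the middle level are recorded and
#' enter the psychometric function like any other level.
#'
#' @param truth a [behavior_truth()] object.
#' @param grid a [build_condition_grid()] data frame.
#' @param seed integer seed.
#' @param timepoint_h muscimol time point in hours (NULL for
#'   microstimulation sessions; 0 = pre-injection).
#' @param injection_index 0-based injection repeat index.
#' @param session_id character id stamped on every trial.
#' @return a data frame of class `behavior_trials`: the grid columns plus
#'   `session_id`, `choice` (`"glossier"`/`"less_glossy"`), `rewarded`, and
#'   `timepoint_h` (NA for microstim sessions). The latent parameters are
#'   attached as attribute `manifest`.
#' @export
simulate_session_choices <- function(truth, grid, seed, timepoint_h = NULL,
                                     injection_index = 0L, session_id = "s1") {
  gp_check(inherits(truth, "behavior_truth"), "truth must be a behavior_truth")
  gp_check(is.data.frame(grid) &&
             all(c("gloss_level", "shape_id", "illumination_id", "stimulation")
                 %in% names(grid)),
           "grid must be a condition_grid-like data frame")
  gp_check(is.numeric(injection_index) && length(injection_index) == 1L &&
             injection_index >= 0 && injection_index == trunc(injection_index),
           "injection_index must be a non-negative integer")

  a_eff <- rep(truth$a, nrow(grid))
  b_eff <- rep(truth$b, nrow(grid))
  stim <- as.logical(grid$stimulation)
  a_eff[stim] <- truth$a * truth$stim_slope_factor
  b_eff[stim] <- truth$b + truth$delta_b_stim
  tp <- NA_real_
  if (!is.null(timepoint_h)) {
    tp <- as.numeric(timepoint_h)
    a_eff <- a_eff * muscimol_multiplier(truth, tp, injection_index)
  }
  gp_check(all(a_eff > 0), "effective slope a must remain positive")

  p_glossier <- plogis(a_eff * (grid$gloss_level - b_eff))
  mid <- stats::median(range(grid$gloss_level))
  out <- with_rng(seed, {
    glossier <- rbinom(nrow(grid), 1L, p_glossier) == 1L
    correct <- ifelse(grid$gloss_level > mid, glossier,
                      ifelse(grid$gloss_level < mid, !glossier, NA))
    random_reward <- rbinom(nrow(grid), 1L, 0.5) == 1L
    data.frame(
      session_id = session_id,
      gloss_level = grid$gloss_level,
      shape_id = grid$shape_id,
      illumination_id = grid$illumination_id,
      stimulation = stim,
      choice = ifelse(glossier, "glossier", "less_glossy"),
      rewarded = ifelse(is.na(correct), random_reward, correct),
      timepoint_h = tp,
      stringsAsFactors = FALSE
    )
  })
  structure(out,
            manifest = list(truth = unclass(truth), seed = seed,
                            timepoint_h = tp,
                            injection_index = as.integer(injection_index),
                            session_id = session_id),
            class = c("behavior_trials", "data.frame"))
}

#' Simulate a muscimol injection series
#'
#' One session per time point of the muscimol schedule, canonically the
#' pre-injection baseline (0 h) and 0.5 h, 18 h and 42 h after injection,
#' run on the no-stimulation condition grid (105 conditions). With the
#' default slope-multiplier profile the deficit is largest at 18 h and has
#' recovered fully by 42 h.
#'
#' @param truth a [behavior_truth()] object; its `muscimol_profile` must
#'   cover every time point.
#' @param grid_no_stim condition grid without the stimulation factor.
#' @param seeds integer vector, one seed per time point.
#' @param timepoints time points in hours; 0 denotes pre-injection.
#' @param injection_index 0-based injection repeat index.
#' @param site_id id prefix for session ids.
#' @return a `behavior_trials` data frame stacking all time-point sessions,
#'   with a combined `manifest` attribute.
#' @export
simulate_muscimol_series <- function(truth, grid_no_stim, seeds,
                                     timepoints = c(0, 0.5, 18, 42),
                                     injection_index = 0L, site_id = "site1") {
  gp_check(length(seeds) == length(timepoints),
           "seeds must have one entry per time point")
  gp_check(!any(as.logical(grid_no_stim$stimulation)),
           "muscimol series uses the no-stimulation grid")
  keys <- tp_key(timepoints)
  missing <- setdiff(keys, names(truth$muscimol_profile))
  gp_check(length(missing) == 0,
           paste0("muscimol_profile missing time points: ",
                  paste(missing, collapse = ", ")))

  sessions <- lapply(seq_along(timepoints), function(i) {
    simulate_session_choices(
      truth, grid_no_stim, seed = seeds[i], timepoint_h = timepoints[i],
      injection_index = injection_index,
      session_id = sprintf("%s_inj%d_t%s", site_id, injection_index, keys[i])
    )
  })
  out <- do.call(rbind, lapply(sessions, as.data.frame))
  structure(out,
            manifest = list(truth = unclass(truth), seeds = seeds,
                            timepoints = timepoints,
                            injection_index = as.integer(injection_index),
                            site_id = site_id),
            class = c("behavior_trials", "data.frame"))
}
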