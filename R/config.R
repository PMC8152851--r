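#' Build a validated pipeline run configuration
#'
#' Collects every tunable parameter of the design, simulation and analysis
#' stages with the canonical task values as defaults, validates them, and
#' supports lossless JSON round-tripping for reproducible runs. Every
#' stochastic step derives its seed from the single `seed` field.
#'
#' @param c_min,c_max gloss-contrast range (defaults: the 0.029--0.119
#'   ladder).
#' @param n_levels gloss levels (7).
#' @param cd_ratio Δc/Δd (1.78).
#' @param d_anchor `d` at level 1 (0).
#' @param n_shapes shape complexity levels per daily set (5).
#' @param basis_order spherical-harmonics order (6).
#' @param illuminations illumination ids.
#' @param reference_illumination_mode `"fixed"` (reference always rendered
#'   under the first illumination) or `"matched"` (reference illumination
#'   follows the test stimulus). Recorded for fidelity; it does not enter
#'   the generative model.
#' @param alpha significance level for every test (0.05).
#' @param n_perm permutations per test (10000).
#' @param tail_criterion one-sided permutation tail mass (0.025).
#' @param response_window_s,baseline_window_s spike-count windows (0.3 s).
#' @param exclusion_rms psychometric-fit exclusion threshold (0.25).
#' @param a_true,b_true behavioral ground-truth logistic parameters.
#' @param delta_b_stim per-session stimulation offset shifts (recycled over
#'   sessions; 0 = no effect).
#' @param stim_slope_factor stimulation slope factor (1).
#' @param muscimol_profile named slope-multiplier profile.
#' @param injection_attenuation per-repeat deficit multiplier (1).
#' @param n_sessions microstimulation sessions to simulate (53).
#' @param n_injections muscimol injections per site (1).
#' @param timepoints muscimol schedule in hours (0 = pre-injection).
#' @param seed master seed.
#' @return an object of class `gloss_config` (a named list).
#' @export
gloss_config <- function(c_min = 0.029, c_max = 0.119, n_levels = 7L,
                         cd_ratio = 1.78, d_anchor = 0,
                         n_shapes = 5L, basis_order = 6L,
                         illuminations = c("Eucalyptus", "Campus", "Building"),
                         reference_illumination_mode = c("fixed", "matched"),
                         alpha = 0.05, n_perm = 10000L, tail_criterion = 0.025,
                         response_window_s = 0.3, baseline_window_s = 0.3,
                         exclusion_rms = 0.25,
                         a_true = 1, b_true = 4,
                         delta_b_stim = 0, stim_slope_factor = 1,
                         muscimol_profile = c("0" = 1, "0.5" = 0.8,
                                              "18" = 0.4, "42" = 1.0),
                         injection_attenuation = 1,
                         n_sessions = 53L, n_injections = 1L,
                         timepoints = c(0, 0.5, 18, 42),
                         seed = 1L) {
  cfg <- structure(list(
    c_min = c_min, c_max = c_max, n_levels = as.integer(n_levels),
    cd_ratio = cd_ratio, d_anchor = d_anchor,
    n_shapes = as.integer(n_shapes), basis_order = as.integer(basis_order),
    illuminations = illuminations,
    reference_illumination_mode = match.arg(reference_illumination_mode),
    alpha = alpha, n_perm = as.integer(n_perm),
    tail_criterion = tail_criterion,
    response_window_s = response_window_s,
    baseline_window_s = baseline_window_s,
    exclusion_rms = exclusion_rms,
    a_true = a_true, b_true = b_true,
    delta_b_stim = delta_b_stim, stim_slope_factor = stim_slope_factor,
    muscimol_profile = muscimol_profile,
    injection_attenuation = injection_attenuation,
    n_sessions = as.integer(n_sessions),
    n_injections = as.integer(n_injections),
    timepoints = timepoints, seed = as.integer(seed)
  ), class = "gloss_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `gloss_config` (or compatible list).
#' @return `cfg`, invisibly; signals a validation error otherwise.
#' @export
validate_config <- function(cfg) {
  gp_check(is.list(cfg), "config must be a list")
  req <- c("c_min", "c_max", "n_levels", "cd_ratio", "alpha", "n_perm",
           "seed", "a_true", "b_true", "muscimol_profile", "timepoints")
  missing <- setdiff(req, names(cfg))
  gp_check(length(missing) == 0,
           paste0("config missing fields: ", paste(missing, collapse = ", ")))
  gp_check(cfg$c_max > cfg$c_min, "config: c_max must exceed c_min")
  gp_check(cfg$cd_ratio > 0, "config: cd_ratio must be positive")
  gp_check(cfg$alpha > 0 && cfg$alpha < 1, "config: alpha must be in (0, 1)")
  gp_check(is_count(cfg$n_perm), "config: n_perm must be a positive integer")
  gp_check(cfg$a_true > 0, "config: a_true must be positive")
  gp_check(length(cfg$illuminations) >= 1, "config: need >= 1 illumination")
  gp_check(abs(cfg$seed) < 2^31, "config: seed must fit 32 bits")
  # truth construction revalidates the behavioral parameters
  config_truth(cfg)
  invisible(cfg)
}

#' @noRd
config_truth <- function(cfg, delta_b_stim = NULL) {
  behavior_truth(
    a = cfg$a_true, b = cfg$b_true,
    delta_b_stim = if (is.null(delta_b_stim)) cfg$delta_b_stim[1L] else delta_b_stim,
    stim_slope_factor = cfg$stim_slope_factor,
    muscimol_profile = unlist(cfg$muscimol_profile),
    injection_attenuation = cfg$injection_attenuation
  )
}

#' Serialize a configuration to JSON
#' @param cfg a `gloss_config`.
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
config_to_json <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Load a configuration from JSON
#' @param path path to a JSON file (or a JSON string).
#' @return a validated `gloss_config`.
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$muscimol_profile <- unlist(raw$muscimol_profile)
  base <- gloss_config()
  cfg <- structure(modifyList(unclass(base), raw), class = "gloss_config")
  for (nm in c("n_levels", "n_shapes", "basis_order", "n_perm", "n_sessions",
               "n_injections", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  validate_config(cfg)
  cfg
}

#' Short provenance hash of a configuration
#' @param cfg a `gloss_config`.
#' @return 8-hex-digit FNV-1a hash of the canonical JSON serialization.
#' @export
config_hash <- function(cfg) {
  fnv1a32(jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE, digits = NA))
}

# canonical serializable form: named vectors become named lists so JSON
# keeps their names
#' @noRd
config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$muscimol_profile <- as.list(out$muscimol_profile)
  out
}
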