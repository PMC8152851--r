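# Shared fixtures, built in code at test time.

canonical_ladder <- function() build_gloss_ladder(0.029, 0.119)

canonical_shapes <- function(seed = 1L) generate_shape_set(seed)

canonical_grid <- function(stim = TRUE, seed = 1L) {
  build_condition_grid(canonical_ladder(), canonical_shapes(seed),
                       include_stimulation_factor = stim)
}

canonical_selectivity_set <- function(seed = 1L) {
  sh <- canonical_shapes(seed)
  build_selectivity_stimulus_set(canonical_ladder(), sh,
                                 shuffled_shape_id = shape_ids(sh)[1L])
}

# Hand-build a tuning_curve with given per-level mean responses; per-repeat
# values are the mean plus a tiny fixed jitter so ANOVA is well defined.
make_curve <- function(shape_id, means, n_rep = 6L, shuffled = FALSE,
                       noise = 0.01, unit_id = "u") {
  lv <- seq_along(means)
  jit <- seq(-noise, noise, length.out = n_rep)
  structure(list(
    unit_id = unit_id, shape_id = shape_id, shuffled = shuffled,
    levels = lv,
    mean_response = means + mean(jit),
    responses = lapply(means, function(m) m + jit),
    n_repeats = rep(n_rep, length(means))
  ), class = "tuning_curve")
}

as_curve_set <- function(...) structure(list(...), class = "tuning_curve_set")

# One simulated microstim session split into its two condition tables.
simulate_split_session <- function(truth, seed, grid = canonical_grid()) {
  tr <- simulate_session_choices(truth, grid, seed = seed)
  list(stim = tr[tr$stimulation, ], ctrl = tr[!tr$stimulation, ],
       trials = tr)
}
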