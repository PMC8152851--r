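test_that("unit simulator matches its Poisson generative model", {
  sel <- canonical_selectivity_set()
  ids <- shape_ids(canonical_shapes())
  unit <- unit_truth(base_rate = 10, gains = setNames(rep(40, 5), ids))
  rec <- simulate_unit_responses(unit, sel, n_repeats = 100, seed = 3)

  # determinism
  rec2 <- simulate_unit_responses(unit, sel, n_repeats = 100, seed = 3)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))

  # level-7 object responses: rate 10 + 40 = 50 spk/s -> mean count 15 in
  # 300 ms; Poisson SE of the mean over n reps is sqrt(mu / n)
  top <- rec[!rec$shuffled & rec$gloss_level == 7, ]
  mu <- 15
  se <- sqrt(mu / length(top$response_count))
  expect_lt(abs(mean(top$response_count) - mu), 3 * se * sqrt(5))  # 5 shapes pooled

  # shuffled responses flat at base rate under confound_mode = "none"
  shuf <- rec[rec$shuffled, ]
  expect_lt(abs(mean(shuf$response_count) - 10 * 0.3),
            3 * sqrt(10 * 0.3 / nrow(shuf)))

  # Poisson dispersion: variance/mean ~ 1 per stimulus cell
  cells <- split(top$response_count, top$shape_id)
  vm <- vapply(cells, function(x) var(x) / mean(x), 0)
  expect_true(all(abs(vm - 1) < 0.5))
})

test_that("unit simulator validates inputs and flat units look flat", {
  sel <- canonical_selectivity_set()
  ids <- shape_ids(canonical_shapes())
  expect_error(
    simulate_unit_responses(unit_truth(gains = setNames(rep(10, 5), ids)),
                            sel, n_repeats = 4, seed = 1),
    class = "glossperm_validation_error")
  expect_error(
    simulate_unit_responses(
      unit_truth(base_rate = 5, gains = setNames(rep(-50, 5), ids)),
      sel, n_repeats = 10, seed = 1),
    class = "glossperm_validation_error")

  flat <- simulate_unit_responses(
    unit_truth(base_rate = 40, gains = setNames(rep(0, 5), ids)),
    sel, n_repeats = 50, seed = 9)
  r <- compute_trial_response(flat)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("choice generator follows its logistic truth", {
  truth <- behavior_truth(a = 1, b = 4)
  grid <- canonical_grid()
  # pool many sessions: empirical P(glossier | level) converges to the
  # generator logistic
  seeds <- seed_schedule(5, 40)
  trials <- do.call(rbind, lapply(seeds, function(s)
    as.data.frame(simulate_session_choices(truth, grid, seed = s))))
  tab <- aggregate_choice_proportions(trials, "none")
  expected <- plogis(1 * (tab$gloss_level - 4))
  se <- sqrt(expected * (1 - expected) / tab$n_trials)
  expect_true(all(abs(tab$proportion - expected) < 4 * se))

  # step-function limit: a huge -> deterministic choices away from b
  hard <- simulate_session_choices(behavior_truth(a = 50, b = 4), grid, seed = 1)
  expect_true(all(hard$choice[hard$gloss_level >= 5] == "glossier"))
  expect_true(all(hard$choice[hard$gloss_level <= 3] == "less_glossy"))
})

test_that("middle-level trials are randomly rewarded, others by correctness", {
  truth <- behavior_truth(a = 1, b = 4)
  grid <- canonical_grid()
  seeds <- seed_schedule(11, 30)
  trials <- do.call(rbind, lapply(seeds, function(s)
    as.data.frame(simulate_session_choices(truth, grid, seed = s))))
  hi <- trials[trials$gloss_level > 4, ]
  lo <- trials[trials$gloss_level < 4, ]
  expect_true(all(hi$rewarded == (hi$choice == "glossier")))
  expect_true(all(lo$rewarded == (lo$choice == "less_glossy")))
  mid <- trials[trials$gloss_level == 4, ]
  p_rew <- mean(mid$rewarded)
  expect_lt(abs(p_rew - 0.5), 4 * sqrt(0.25 / nrow(mid)))
  # reward at level 4 is independent of the choice made
  p_by_choice <- tapply(mid$rewarded, mid$choice, mean)
  expect_lt(abs(diff(p_by_choice)), 0.15)
})

test_that("stimulation offset shifts are recovered without bias", {
  # generator inversion: fitted offset difference averages to delta_b_stim
  truth <- behavior_truth(a = 1, b = 4, delta_b_stim = -1)
  grid <- canonical_grid()
  seeds <- seed_schedule(23, 400)
  dbs <- vapply(seeds, function(s) {
    tr <- simulate_session_choices(truth, grid, seed = s)
    tab <- aggregate_choice_proportions(tr, "stimulation")
    fit_logistic(tab[tab$group == "stim", ])$b -
      fit_logistic(tab[tab$group == "no_stim", ])$b
  }, 0)
  se <- sd(dbs) / sqrt(length(dbs))
  expect_lt(abs(mean(dbs) - (-1)), 3 * se)
})

test_that("muscimol slope multipliers follow the attenuation rule", {
  truth <- behavior_truth(injection_attenuation = 0.5)
  # closed form of the generator's own rule: second injection at 18 h
  # has multiplier 1 - (1 - 0.4) * 0.5 = 0.7
  expect_equal(glossperm:::muscimol_multiplier(truth, 18, 1L), 0.7)
  expect_equal(glossperm:::muscimol_multiplier(truth, 18, 0L), 0.4)
  expect_equal(glossperm:::muscimol_multiplier(truth, 42, 0L), 1.0)
  expect_error(glossperm:::muscimol_multiplier(truth, 7, 0L),
               class = "glossperm_validation_error")
})

test_that("muscimol series place the largest expected slope deficit at 18 h", {
  grid <- canonical_grid(stim = FALSE)
  truth <- behavior_truth()
  reps <- 120
  seeds <- seed_schedule(31, reps * 4)
  diffs <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    ser <- simulate_muscimol_series(truth, grid,
                                    seeds = seeds[(i - 1) * 4 + 1:4])
    tab <- aggregate_choice_proportions(ser, "timepoint")
    a_pre <- fit_logistic(tab[tab$group == "0", ])$a
    diffs[i, ] <- vapply(c("0.5", "18", "42"), function(k)
      fit_logistic(tab[tab$group == k, ])$a - a_pre, 0)
  }
  m <- colMeans(diffs)
  expect_true(which.min(m) == 2)          # deficit maximal at 18 h
  expect_lt(abs(m[3]), 3 * sd(diffs[, 3]) / sqrt(reps))  # recovered at 42 h
  # null profile: all sessions exchangeable in expectation
  null_truth <- behavior_truth(muscimol_profile = c("0" = 1, "0.5" = 1,
                                                    "18" = 1, "42" = 1))
  ser <- simulate_muscimol_series(null_truth, grid, seeds = seed_schedule(2, 4))
  expect_true(all(is.finite(ser$timepoint_h)))
  expect_error(simulate_muscimol_series(truth, grid, seeds = 1:3),
               class = "glossperm_validation_error")
})

test_that("simulated datasets carry ground-truth manifests", {
  grid <- canonical_grid()
  tr <- simulate_session_choices(behavior_truth(), grid, seed = 4)
  man <- attr(tr, "manifest")
  expect_equal(man$truth$a, 1)
  expect_equal(man$seed, 4)
  rec <- simulate_unit_responses(
    unit_truth(gains = setNames(rep(10, 5), shape_ids(canonical_shapes()))),
    canonical_selectivity_set(), n_repeats = 5, seed = 8)
  expect_equal(attr(rec, "manifest")$seed, 8)
  expect_equal(attr(rec, "response_window_s"), 0.3)
})
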