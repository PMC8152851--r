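test_that("baseline-subtracted rates follow the window arithmetic", {
  rec <- data.frame(response_count = c(15L, 12L, 0L),
                    baseline_count = c(12L, 12L, 12L))
  attr(rec, "response_window_s") <- 0.3
  attr(rec, "baseline_window_s") <- 0.3
  expect_equal(compute_trial_response(rec), c(10, 0, -40))
  attr(rec, "response_window_s") <- 0
  expect_error(compute_trial_response(rec), class = "glossperm_validation_error")
})

test_that("tuning ANOVA agrees with the linear-model oracle", {
  # dual route: our closed-form F / p vs anova(lm(...)) on random curves
  with_rng(17, {
    for (i in 1:10) {
      n_rep <- sample(5:9, 1)
      means <- runif(7, 0, 30)
      y <- unlist(lapply(means, function(m) m + rnorm(n_rep, sd = 5)))
      lv <- rep(1:7, each = n_rep)
      curve <- structure(list(
        unit_id = "u", shape_id = "s", shuffled = FALSE, levels = 1:7,
        mean_response = vapply(split(y, lv), mean, 0),
        responses = split(y, lv), n_repeats = rep(n_rep, 7)),
        class = "tuning_curve")
      got <- tuning_anova(curve)
      oracle <- anova(lm(y ~ factor(lv)))
      expect_equal(got$F, oracle$`F value`[1], tolerance = 1e-10)
      expect_equal(got$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
    }
  })
})

test_that("tuning ANOVA handles degenerate and under-sampled curves", {
  const <- make_curve("s", rep(5, 7), noise = 0)
  expect_equal(tuning_anova(const)$p, 1)
  expect_false(tuning_anova(const)$significant)

  few <- make_curve("s", 1:7, n_rep = 4)
  expect_error(tuning_anova(few), class = "glossperm_exclusion_error")

  strong <- simulate_unit_responses(
    unit_truth(base_rate = 10,
               gains = setNames(rep(40, 5), shape_ids(canonical_shapes()))),
    canonical_selectivity_set(), n_repeats = 10, seed = 2)
  cu <- build_tuning_curves(strong)
  ps <- vapply(Filter(function(c) !c$shuffled, cu),
               function(c) tuning_anova(c)$p, 0)
  expect_true(all(ps < 0.05))
})

test_that("optimal shape is the peak-response argmax with lexicographic ties", {
  one <- as_curve_set(make_curve("only", 1:7))
  expect_equal(select_optimal_shape(one), "only")

  gains <- c(s1 = 10, s2 = 40, s3 = 20, s4 = 5, s5 = 5)
  set <- do.call(as_curve_set, lapply(names(gains), function(id)
    make_curve(id, gains[[id]] * (0:6) / 6)))
  expect_equal(select_optimal_shape(set), "s2")

  tie <- as_curve_set(make_curve("b", c(0, 0, 10), noise = 0),
                      make_curve("a", c(0, 0, 10), noise = 0))
  expect_equal(select_optimal_shape(tie), "a")
})

test_that("classification rule combines ANOVA, correlation and the shuffled control", {
  ids <- shape_ids(canonical_shapes())
  sel <- canonical_selectivity_set()

  gloss <- simulate_unit_responses(
    unit_truth(base_rate = 10, gains = setNames(rep(40, 5), ids)),
    sel, n_repeats = 10, seed = 101)
  res <- classify_unit(build_tuning_curves(gloss))
  expect_s3_class(res, "selectivity_result")
  expect_true(res$is_gloss_selective)
  expect_equal(res$status, "gloss_selective")
  expect_equal(res$preference_sign, "glossy")

  matte <- simulate_unit_responses(
    unit_truth(base_rate = 10, gains = setNames(rep(40, 5), ids), sign = -1),
    sel, n_repeats = 10, seed = 102)
  res_m <- classify_unit(build_tuning_curves(matte))
  expect_true(res_m$is_gloss_selective)
  expect_equal(res_m$preference_sign, "matte")

  confound <- simulate_unit_responses(
    unit_truth(base_rate = 10, gains = setNames(rep(40, 5), ids),
               confound_mode = "luminance"),
    sel, n_repeats = 10, seed = 103)
  res_c <- classify_unit(build_tuning_curves(confound))
  expect_false(res_c$is_gloss_selective)

  flat <- simulate_unit_responses(
    unit_truth(base_rate = 40, gains = setNames(rep(0, 5), ids)),
    sel, n_repeats = 10, seed = 104)
  expect_false(classify_unit(build_tuning_curves(flat))$is_gloss_selective)
})

test_that("classification edge cases are reported, not silently passed", {
  # significant tuning only for the optimal shape: not classifiable
  set <- as_curve_set(make_curve("opt", (1:7) * 4, noise = 0.5),
                      make_curve("flat", rep(1, 7), noise = 0.5),
                      make_curve("shuf", rep(1, 7), noise = 0.5, shuffled = TRUE))
  res <- classify_unit(set)
  expect_equal(res$status, "not_classifiable")
  expect_false(res$is_gloss_selective)

  # shuffled data required but missing -> classification error
  two <- as_curve_set(make_curve("a", (1:7) * 4, noise = 0.5),
                      make_curve("b", (1:7) * 3, noise = 0.5))
  expect_error(classify_unit(two), class = "glossperm_classification_error")
})

test_that("repeat order is exchangeable (permutation of rows changes nothing)", {
  rec <- simulate_unit_responses(
    unit_truth(base_rate = 10,
               gains = setNames(rep(40, 5), shape_ids(canonical_shapes()))),
    canonical_selectivity_set(), n_repeats = 8, seed = 77)
  res1 <- classify_unit(build_tuning_curves(rec))
  shuffled_rows <- rec[with_rng(1, sample.int(nrow(rec))), ]
  attr(shuffled_rows, "response_window_s") <- attr(rec, "response_window_s")
  attr(shuffled_rows, "baseline_window_s") <- attr(rec, "baseline_window_s")
  res2 <- classify_unit(build_tuning_curves(shuffled_rows))
  expect_equal(res1$status, res2$status)
  expect_equal(res1$optimal_shape_id, res2$optimal_shape_id)
  expect_equal(res1$anova_p, res2$anova_p)
})

test_that("preference sign follows the rank correlation of the optimal tuning", {
  expect_equal(preference_sign(make_curve("s", 1:7, noise = 0)), "glossy")
  expect_equal(preference_sign(make_curve("s", 7:1, noise = 0)), "matte")
  expect_equal(preference_sign(make_curve("s", rep(2, 7), noise = 0)), "undefined")
})
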