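test_that("identical condition and control tables give zero, non-significant deltas", {
  tr <- simulate_session_choices(behavior_truth(), canonical_grid(), seed = 2)
  ctrl <- tr[!tr$stimulation, ]
  res <- permutation_test(ctrl, ctrl, n_perm = 300, seed = 5)
  expect_equal(res$delta_a, 0)
  expect_equal(res$delta_b, 0)
  expect_false(res$significant_a)
  expect_false(res$significant_b)
})

test_that("permutation results are seed-deterministic and validated", {
  s <- simulate_split_session(behavior_truth(delta_b_stim = -1), seed = 3)
  r1 <- permutation_test(s$stim, s$ctrl, n_perm = 300, seed = 11)
  r2 <- permutation_test(s$stim, s$ctrl, n_perm = 300, seed = 11)
  expect_identical(r1$null_delta_b, r2$null_delta_b)
  expect_identical(r1$p_b, r2$p_b)
  r3 <- permutation_test(s$stim, s$ctrl, n_perm = 300, seed = 12)
  expect_false(identical(r1$null_delta_b, r3$null_delta_b))

  expect_error(permutation_test(s$stim[-1, ], s$ctrl, n_perm = 100, seed = 1),
               class = "glossperm_validation_error")
  expect_length(r1$null_delta_a, 300 - r1$n_dropped)
})

test_that("significance flags match the 2.5% tail-rank criterion", {
  s <- simulate_split_session(behavior_truth(delta_b_stim = -1.5), seed = 8)
  for (mode in c("complement", "independent")) {
    res <- permutation_test(s$stim, s$ctrl, n_perm = 500, seed = 21, mode = mode)
    null <- res$null_delta_b
    m <- length(null)
    in_tail <- min((1 + sum(null <= res$delta_b)) / (m + 1),
                   (1 + sum(null >= res$delta_b)) / (m + 1)) <= 0.025
    expect_identical(res$significant_b, in_tail)
    expect_true(res$p_b >= 0 && res$p_b <= 1)
  }
})

test_that("shift direction follows the offset sign convention of the generator", {
  # delta_b_stim < 0 raises P(glossier) on stimulated trials
  s <- simulate_split_session(behavior_truth(delta_b_stim = -1.5), seed = 8)
  res <- permutation_test(s$stim, s$ctrl, n_perm = 1000, seed = 4)
  expect_true(res$significant_b)
  expect_lt(res$delta_b, 0)
  expect_equal(classify_shift_direction(res), "glossier")

  s2 <- simulate_split_session(behavior_truth(delta_b_stim = 1.5), seed = 8)
  res2 <- permutation_test(s2$stim, s2$ctrl, n_perm = 1000, seed = 4)
  expect_true(res2$significant_b)
  expect_equal(classify_shift_direction(res2), "less_glossy")

  res$significant_b <- FALSE
  expect_equal(classify_shift_direction(res), "none")
})

test_that("null permutation p-values are close to uniform (exchangeability)", {
  truth <- behavior_truth(a = 1, b = 4)
  grid <- canonical_grid()
  reps <- 150
  seeds <- seed_schedule(41, 2 * reps)
  pv <- vapply(seq_len(reps), function(i) {
    tr <- simulate_session_choices(truth, grid, seed = seeds[i])
    permutation_test(tr[tr$stimulation, ], tr[!tr$stimulation, ],
                     n_perm = 199, seed = seeds[reps + i])$p_b
  }, 0)
  # KS distance to U(0,1); bound chosen a priori for n = 150 plus the
  # discreteness of 199 permutations and the conservative add-one p
  ks <- max(abs(sort(pv) - (seq_len(reps)) / reps))
  expect_lt(ks, 0.15)
  expect_gt(mean(pv), 0.40)
})

test_that("power grows with the injected offset shift (property)", {
  grid <- canonical_grid()
  reps <- 50
  seeds <- seed_schedule(53, 2 * reps)
  rate <- vapply(c(0, -0.75, -1.5), function(db) {
    truth <- behavior_truth(a = 1, b = 4, delta_b_stim = db)
    mean(vapply(seq_len(reps), function(i) {
      tr <- simulate_session_choices(truth, grid, seed = seeds[i])
      permutation_test(tr[tr$stimulation, ], tr[!tr$stimulation, ],
                       n_perm = 250, seed = seeds[reps + i])$significant_b
    }, NA))
  }, 0)
  expect_true(all(diff(rate) > -0.08))  # non-decreasing up to MC noise
  expect_gt(rate[3], rate[1])
})

test_that("slope timecourse needs a pre-session and reports per time point", {
  grid <- canonical_grid(stim = FALSE)
  ser <- simulate_muscimol_series(behavior_truth(), grid,
                                  seeds = seed_schedule(61, 4))
  tc <- slope_timecourse(ser, n_perm = 200, seed = 9)
  expect_s3_class(tc, "timecourse")
  expect_equal(tc$timepoint_h, c(0.5, 18, 42))
  expect_true(all(is.finite(tc$slope_difference)))

  post_only <- ser[ser$timepoint_h > 0, ]
  expect_error(slope_timecourse(post_only, n_perm = 100, seed = 1),
               class = "glossperm_validation_error")
})

test_that("repeated-injection summaries expose attenuation trends", {
  fake_tc <- function(diff18) {
    structure(data.frame(timepoint_h = c(0.5, 18, 42),
                         slope_difference = c(diff18 / 2, diff18, 0),
                         p_slope = c(0.5, 0.01, 0.9),
                         significant = c(FALSE, TRUE, FALSE),
                         delta_b = 0, p_b = 1, n_dropped = 0L,
                         unreliable = FALSE),
              class = c("timecourse", "data.frame"))
  }
  one <- repeated_injection_summary(list(fake_tc(-0.6)))
  expect_equal(nrow(one), 1)
  expect_true(is.na(attr(one, "trend")))

  three <- repeated_injection_summary(list(fake_tc(-0.6), fake_tc(-0.3),
                                           fake_tc(-0.15)))
  expect_equal(three$slope_difference, c(-0.6, -0.3, -0.15))
  expect_equal(attr(three, "trend"), -1)
  expect_error(repeated_injection_summary(list(fake_tc(-1)), at_timepoint_h = 99),
               class = "glossperm_validation_error")
})
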