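# Coerce a trial table (or prepared samples) to per-trial binary outcomes.
#' @noRd
as_choice_samples <- function(x) {
  gp_check(is.data.frame(x) && "gloss_level" %in% names(x),
           "samples must be a data frame with a gloss_level column")
  if ("choice" %in% names(x)) {
    gp_check(all(x$choice %in% c("glossier", "less_glossy")),
             "choice must be 'glossier' or 'less_glossy'")
    y <- as.integer(x$choice == "glossier")
  } else if ("glossier" %in% names(x)) {
    y <- as.integer(x$glossier)
    gp_check(all(y %in% c(0L, 1L)), "glossier must be binary")
  } else gp_stop("samples need a 'choice' or binary 'glossier' column")
  data.frame(gloss_level = x$gloss_level, glossier = y)
}

#' Permutation test for psychometric parameter differences
#'
#' Tests whether the logistic slope `a` and offset `b` differ between two
#' conditions of one session (stimulation vs. no stimulation, or after vs.
#' before a muscimol injection). At every gloss level the two conditions
#' contribute equal numbers of binary choice samples (canonically 15 + 15 =
#' 30, one per shape x illumination). Each permutation pools the per-level
#' samples and randomly reassigns them to two pseudo-groups of the original
#' sizes — by default drawing one group and giving its complement to the
#' other, a true permutation that preserves exchangeability exactly
#' (`mode = "independent"` instead draws both groups independently without
#' replacement). Both pseudo-groups are refit and the parameter differences
#' recorded, building null distributions of Δa and Δb. The observed
#' difference is significant when it lies within the extreme 2.5% of either
#' end of its null distribution; two-tailed p-values use rank-based tail
#' proportions that include the observed value (the add-one convention, so
#' p is never exactly 0). Permutation fits that fail to converge are
#' dropped from the null with a logged count; if more than 5% fail the
#' result is flagged unreliable.
#'
#' Resampling is done per level on pooled success counts (hypergeometric
#' draws), which is exactly equivalent to permuting the individual binary
#' samples and considerably faster.
#'
#' @param samples_condition,samples_control trial tables for the two
#'   conditions (data frames with `gloss_level` and `choice` or binary
#'   `glossier` columns).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param mode `"complement"` (default) or `"independent"`; see above.
#' @param tail_criterion one-sided tail mass defining significance
#'   (default 0.025, i.e. a 5% two-tailed criterion).
#' @return an object of class `permutation_result`: list with `delta_a`,
#'   `delta_b`, `null_delta_a`, `null_delta_b`, `p_a`, `p_b`,
#'   `significant_a`, `significant_b`, `fit_condition`, `fit_control`,
#'   `n_perm`, `n_dropped`, `unreliable`, `seed`.
#' @export
permutation_test <- function(samples_condition, samples_control,
                             n_perm = 10000L, seed = 1L,
                             mode = c("complement", "independent"),
                             tail_criterion = 0.025) {
  mode <- match.arg(mode)
  gp_check(is_count(n_perm), "n_perm must be a positive integer")
  gp_check(tail_criterion > 0 && tail_criterion < 0.5,
           "tail_criterion must be in (0, 0.5)")
  A <- as_choice_samples(samples_condition)
  B <- as_choice_samples(samples_control)

  lv <- sort(unique(c(A$gloss_level, B$gloss_level)))
  nA <- vapply(lv, function(l) sum(A$gloss_level == l), 0L)
  nB <- vapply(lv, function(l) sum(B$gloss_level == l), 0L)
  gp_check(all(nA > 0) && all(nB > 0),
           "both conditions must have samples at every gloss level")
  gp_check(all(nA == nB),
           "condition and control must contribute equal sample counts per level")
  sA <- vapply(lv, function(l) sum(A$glossier[A$gloss_level == l]), 0L)
  sB <- vapply(lv, function(l) sum(B$glossier[B$gloss_level == l]), 0L)

  fitA <- fit_logistic(data.frame(gloss_level = lv, proportion = sA / nA))
  fitB <- fit_logistic(data.frame(gloss_level = lv, proportion = sB / nB))
  delta_a <- fitA$a - fitB$a
  delta_b <- fitA$b - fitB$b

  s <- sA + sB
  n <- nA + nB
  nL <- length(lv)
  # per-level pseudo-group success counts, n_perm x n_levels
  perm <- with_rng(seed, {
    kA <- matrix(0L, n_perm, nL)
    kB <- matrix(0L, n_perm, nL)
    for (j in seq_len(nL)) {
      kA[, j] <- rhyper(n_perm, s[j], n[j] - s[j], nA[j])
      kB[, j] <- if (mode == "complement") s[j] - kA[, j]
                 else rhyper(n_perm, s[j], n[j] - s[j], nB[j])
    }
    list(kA = kA, kB = kB)
  })
  null_a <- null_b <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    fa <- logistic_ls_core(lv, perm$kA[i, ] / nA)
    fb <- logistic_ls_core(lv, perm$kB[i, ] / nB)
    if (fa$converged && fb$converged) {
      null_a[i] <- fa$a - fb$a
      null_b[i] <- fa$b - fb$b
    }
  }
  keep <- !is.na(null_a)
  n_dropped <- sum(!keep)
  null_a <- null_a[keep]
  null_b <- null_b[keep]
  gp_check(length(null_a) > 0, "all permutation fits failed",
           class = "glossperm_runtime_error")

  two_tailed <- function(obs, null) {
    m <- length(null)
    p_lo <- (1 + sum(null <= obs)) / (m + 1)
    p_hi <- (1 + sum(null >= obs)) / (m + 1)
    list(p = min(1, 2 * min(p_lo, p_hi)),
         significant = min(p_lo, p_hi) <= tail_criterion)
  }
  ta <- two_tailed(delta_a, null_a)
  tb <- two_tailed(delta_b, null_b)

  structure(list(delta_a = delta_a, delta_b = delta_b,
                 null_delta_a = null_a, null_delta_b = null_b,
                 p_a = ta$p, p_b = tb$p,
                 significant_a = ta$significant, significant_b = tb$significant,
                 fit_condition = fitA, fit_control = fitB,
                 n_perm = as.integer(n_perm), n_dropped = n_dropped,
                 unreliable = n_dropped > 0.05 * n_perm,
                 mode = mode, tail_criterion = tail_criterion,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> Δa = %.4f (p = %.4f%s), ",
                     "Δb = %.4f (p = %.4f%s); %d permutations, %d dropped%s\n"),
              x$delta_a, x$p_a, if (x$significant_a) " *" else "",
              x$delta_b, x$p_b, if (x$significant_b) " *" else "",
              x$n_perm, x$n_dropped,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Direction of a significant psychometric shift
#'
#' A significant negative offset difference (condition minus control) moves
#' the 50% point toward lower test-gloss levels, i.e. the subject judges
#' the test stimulus glossier under the condition; a positive significant
#' difference is a bias toward less-glossy judgments.
#'
#' @param result a `permutation_result`.
#' @return `"glossier"`, `"less_glossy"` or `"none"`.
#' @export
classify_shift_direction <- function(result) {
  gp_check(inherits(result, "permutation_result"),
           "result must be a permutation_result")
  if (!result$significant_b || result$delta_b == 0) return("none")
  if (result$delta_b < 0) "glossier" else "less_glossy"
}

#' Muscimol slope-change time course
#'
#' For each post-injection time point, runs the permutation test with the
#' "after injection" and "before injection" sessions as the two conditions
#' and reports the slope difference `a(post) - a(pre)` with its
#' significance. Only the slope contrast is interpreted for muscimol
#' (inactivation outlasts the trial and affects reference and test stimuli
#' alike, making offset shifts uninterpretable); the offset difference is
#' still computed and reported.
#'
#' @param trials a `behavior_trials` data frame covering the pre-injection
#'   epoch (`timepoint_h == 0`) and one or more post-injection time points.
#' @param n_perm permutations per time point.
#' @param seed integer seed (one sub-seed is derived per time point).
#' @param ... passed on to [permutation_test()].
#' @return a data frame of class `timecourse`: `timepoint_h`,
#'   `slope_difference`, `p_slope`, `significant`, `delta_b`, `p_b`,
#'   `n_dropped`, `unreliable`; permutation results in attribute `results`.
#' @export
slope_timecourse <- function(trials, n_perm = 10000L, seed = 1L, ...) {
  gp_check(is.data.frame(trials) && "timepoint_h" %in% names(trials),
           "trials must carry a timepoint_h column")
  tps <- sort(unique(trials$timepoint_h))
  gp_check(0 %in% tps, "pre-injection session (timepoint_h = 0) is missing")
  post <- setdiff(tps, 0)
  gp_check(length(post) >= 1, "no post-injection sessions present")
  pre_trials <- trials[trials$timepoint_h == 0, ]
  seeds <- seed_schedule(seed, length(post))

  results <- lapply(seq_along(post), function(i) {
    permutation_test(trials[trials$timepoint_h == post[i], ], pre_trials,
                     n_perm = n_perm, seed = seeds[i], ...)
  })
  out <- data.frame(
    timepoint_h = post,
    slope_difference = vapply(results, `[[`, 0, "delta_a"),
    p_slope = vapply(results, `[[`, 0, "p_a"),
    significant = vapply(results, `[[`, NA, "significant_a"),
    delta_b = vapply(results, `[[`, 0, "delta_b"),
    p_b = vapply(results, `[[`, 0, "p_b"),
    n_dropped = vapply(results, `[[`, 0L, "n_dropped"),
    unreliable = vapply(results, `[[`, NA, "unreliable")
  )
  structure(out, results = results, class = c("timecourse", "data.frame"))
}

#' Summary of repeated muscimol injections at one site
#'
#' Collects the 18-h (or other reference time point) slope difference for
#' each successive injection at a site and quantifies attenuation of the
#' effect across repeats as the Spearman correlation between the absolute
#' slope difference and the injection number (negative = the deficit
#' shrinks with repeated injections).
#'
#' @param timecourses list of `timecourse` data frames, one per injection,
#'   in injection order.
#' @param at_timepoint_h reference time point (default 18).
#' @return a data frame of class `injection_summary`: `injection`,
#'   `slope_difference`, `significant`; the attenuation trend statistic is
#'   in attribute `trend` (NA for a single injection).
#' @export
repeated_injection_summary <- function(timecourses, at_timepoint_h = 18) {
  gp_check(is.list(timecourses) && length(timecourses) >= 1 &&
             all(vapply(timecourses, inherits, NA, "timecourse")),
           "timecourses must be a non-empty list of timecourse objects")
  rows <- lapply(seq_along(timecourses), function(i) {
    tc <- timecourses[[i]]
    j <- match(at_timepoint_h, tc$timepoint_h)
    gp_check(!is.na(j), sprintf("injection %d has no %g h time point",
                                i, at_timepoint_h))
    data.frame(injection = i,
               slope_difference = tc$slope_difference[j],
               significant = tc$significant[j])
  })
  out <- do.call(rbind, rows)
  trend <- if (nrow(out) >= 2)
    suppressWarnings(cor(abs(out$slope_difference), out$injection,
                         method = "spearman"))
  else NA_real_
  structure(out, trend = trend, at_timepoint_h = at_timepoint_h,
            class = c("injection_summary", "data.frame"))
}
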