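#' Baseline-subtracted response rate for spike trials
#'
#' The visual response of a trial is the firing rate in the 300-ms window
#' beginning 50 ms after stimulus onset minus the rate in the 300-ms
#' pre-stimulus baseline window, in spikes/s. May be negative.
#'
#' @param records a `spike_trials` data frame (window durations are read
#'   from its attributes, defaulting to 0.3 s each).
#' @return numeric vector of baseline-subtracted rates, one per row.
#' @export
compute_trial_response <- function(records) {
  gp_check(is.data.frame(records) &&
             all(c("response_count", "baseline_count") %in% names(records)),
           "records must have response_count and baseline_count columns")
  rw <- attr(records, "response_window_s"); if (is.null(rw)) rw <- 0.3
  bw <- attr(records, "baseline_window_s"); if (is.null(bw)) bw <- 0.3
  gp_check(is.numeric(rw) && rw > 0 && is.numeric(bw) && bw > 0,
           "window durations must be positive")
  gp_check(all(records$response_count >= 0) && all(records$baseline_count >= 0),
           "spike counts must be non-negative")
  records$response_count / rw - records$baseline_count / bw
}

#' Build per-shape tuning curves from spike trials
#'
#' Groups trials by (shape, shuffled flag) and by gloss level, keeping the
#' per-repeat baseline-subtracted rates as well as their per-level means.
#'
#' @param records a `spike_trials` data frame for one unit.
#' @return a list of class `tuning_curve_set`; each element is a
#'   `tuning_curve` with `unit_id`, `shape_id`, `shuffled`, `levels`,
#'   `mean_response`, `responses` (list of per-repeat rates per level) and
#'   `n_repeats`.
#' @export
build_tuning_curves <- function(records) {
  gp_check(is.data.frame(records) &&
             all(c("unit_id", "shape_id", "shuffled", "gloss_level") %in% names(records)),
           "records must be a spike_trials-like data frame")
  gp_check(length(unique(records$unit_id)) == 1L,
           "build_tuning_curves expects records from a single unit")
  rate <- compute_trial_response(records)
  key <- paste(records$shape_id, records$shuffled)
  curves <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    sub <- records[idx, ]
    by_level <- split(rate[idx], sub$gloss_level)
    lv <- as.integer(names(by_level))
    o <- order(lv)
    structure(
      list(unit_id = sub$unit_id[1L],
           shape_id = sub$shape_id[1L],
           shuffled = sub$shuffled[1L],
           levels = lv[o],
           mean_response = vapply(by_level, mean, 0)[o],
           responses = by_level[o],
           n_repeats = vapply(by_level, length, 0L)[o]),
      class = "tuning_curve"
    )
  })
  # deterministic order: object shapes by id, shuffled curves last
  shuf <- vapply(curves, `[[`, NA, "shuffled")
  ids <- vapply(curves, `[[`, "", "shape_id")
  structure(unname(curves[order(shuf, ids)]), class = "tuning_curve_set")
}

#' One-way ANOVA for gloss modulation of a tuning curve
#'
#' Tests whether per-repeat responses differ across gloss levels
#' (classical fixed-effects one-way ANOVA on baseline-subtracted rates).
#' Curves with fewer than `min_repeats` repetitions at any level are
#' excluded with an error of class `glossperm_exclusion_error` rather than
#' silently passed.
#'
#' @param curve a `tuning_curve`.
#' @param alpha significance level (default 0.05).
#' @param min_repeats minimum repetitions per level (default 5).
#' @return list with `F`, `df1`, `df2`, `p` and `significant`.
#' @export
tuning_anova <- function(curve, alpha = 0.05, min_repeats = 5L) {
  gp_check(inherits(curve, "tuning_curve"), "curve must be a tuning_curve")
  if (any(curve$n_repeats < min_repeats))
    gp_stop(sprintf("curve %s/%s has a level with fewer than %d repeats",
                    curve$unit_id, curve$shape_id, min_repeats),
            class = "glossperm_exclusion_error")
  gp_check(length(curve$levels) >= 2, "ANOVA needs at least 2 gloss levels")

  y <- curve$responses
  ni <- curve$n_repeats
  mi <- curve$mean_response
  n <- sum(ni)
  gm <- sum(ni * mi) / n
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(seq_along(y), function(i) sum((y[[i]] - mi[i])^2), 0))
  df1 <- length(y) - 1L
  df2 <- n - length(y)
  if (ssw <= 0) {
    # all within-level responses identical: F degenerate
    p <- if (ssb <= 1e-12 * max(1, gm^2)) 1 else 0
    Fv <- if (p == 1) NaN else Inf
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  list(F = Fv, df1 = df1, df2 = df2, p = p, significant = p < alpha)
}

#' Optimal shape of a unit
#'
#' The shape yielding the largest response, defined as the maximum of the
#' per-level mean baseline-subtracted rates over levels. Exact ties are
#' broken toward the lexicographically smallest shape id.
#'
#' @param curves a `tuning_curve_set` (shuffled curves are ignored).
#' @return the optimal `shape_id`.
#' @export
select_optimal_shape <- function(curves) {
  gp_check(inherits(curves, "tuning_curve_set") || is.list(curves),
           "curves must be a tuning_curve_set")
  obj <- Filter(function(cu) !isTRUE(cu$shuffled), curves)
  gp_check(length(obj) >= 1, "need at least one object-shape curve")
  peak <- vapply(obj, function(cu) max(cu$mean_response), 0)
  ids <- vapply(obj, `[[`, "", "shape_id")
  o <- order(-peak, ids)
  ids[o][1L]
}

# Pearson correlation between two tuning curves' per-level means, with a
# two-sided p-value; degenerate (zero-variance) curves return r = NA, p = 1.
#' @noRd
tuning_correlation <- function(m1, m2) {
  if (sd(m1) == 0 || sd(m2) == 0) return(list(r = NA_real_, p = 1))
  ct <- cor.test(m1, m2, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classify a unit as gloss-selective
#'
#' Implements the multiunit gloss-selectivity rule. A site enters the
#' correlation stage only when ANOVA across the 7 gloss levels is
#' significant for the optimal shape and at least one other shape. It is
#' classified gloss-selective when (i) the per-level tuning of the optimal
#' shape correlates significantly (Pearson, two-sided p < alpha, n = 7
#' level means) with that of at least one other significantly modulated
#' shape — or all of them with `require_all = TRUE` — and (ii) the
#' shuffled-image control passes: either the shuffled-image ANOVA is not
#' significant, or the optimal-vs-shuffled tuning correlation is not
#' significant. Sites whose ANOVA is significant only for the optimal shape
#' are reported as `"not_classifiable"`, distinct from `"not_selective"`.
#'
#' @param curves a `tuning_curve_set` for one unit, including a shuffled
#'   curve (required whenever the correlation stage is reached).
#' @param alpha significance level for every test (default 0.05).
#' @param require_all require all other significant shapes to correlate
#'   with the optimal shape (default FALSE: at least one suffices).
#' @param min_repeats minimum repetitions per level (default 5).
#' @return an object of class `selectivity_result`: a list with `unit_id`,
#'   `status` (`"gloss_selective"`, `"not_selective"`,
#'   `"not_classifiable"`), `is_gloss_selective`, `optimal_shape_id`,
#'   `anova_p` (named, incl. `"shuffled"` when present), `correlations`
#'   (data frame of optimal-vs-other r and p), `shuffled_r`, `shuffled_p`,
#'   and `preference_sign` (`"glossy"`, `"matte"` or `"undefined"`).
#' @export
classify_unit <- function(curves, alpha = 0.05, require_all = FALSE,
                          min_repeats = 5L) {
  gp_check(inherits(curves, "tuning_curve_set") || is.list(curves),
           "curves must be a tuning_curve_set")
  obj <- Filter(function(cu) !isTRUE(cu$shuffled), curves)
  shuf <- Filter(function(cu) isTRUE(cu$shuffled), curves)
  gp_check(length(obj) >= 1, "need at least one object-shape curve")
  unit_id <- obj[[1L]]$unit_id

  ids <- vapply(obj, `[[`, "", "shape_id")
  an <- lapply(obj, tuning_anova, alpha = alpha, min_repeats = min_repeats)
  anova_p <- setNames(vapply(an, `[[`, 0, "p"), ids)
  sig <- vapply(an, `[[`, NA, "significant")
  shuffled_p <- NA_real_
  if (length(shuf) >= 1)
    shuffled_p <- tuning_anova(shuf[[1L]], alpha = alpha,
                               min_repeats = min_repeats)$p

  optimal <- select_optimal_shape(curves)
  opt_curve <- obj[[match(optimal, ids)]]
  res <- list(unit_id = unit_id, optimal_shape_id = optimal,
              anova_p = c(anova_p, shuffled = shuffled_p),
              correlations = data.frame(shape_id = character(), r = numeric(),
                                        p = numeric(), stringsAsFactors = FALSE),
              shuffled_r = NA_real_, shuffled_p = NA_real_,
              preference_sign = "undefined", alpha = alpha)

  opt_sig <- sig[match(optimal, ids)]
  others_sig <- ids[sig & ids != optimal]
  if (!opt_sig) {
    res$status <- "not_selective"
  } else if (length(others_sig) == 0) {
    res$status <- "not_classifiable"
  } else {
    if (length(shuf) == 0)
      gp_stop("shuffled-image data required for classification but missing",
              class = "glossperm_classification_error")
    cors <- lapply(others_sig, function(sid) {
      cu <- obj[[match(sid, ids)]]
      tuning_correlation(opt_curve$mean_response, cu$mean_response)
    })
    res$correlations <- data.frame(
      shape_id = others_sig,
      r = vapply(cors, `[[`, 0, "r"),
      p = vapply(cors, `[[`, 0, "p"),
      stringsAsFactors = FALSE)
    cor_sig <- res$correlations$p < alpha & !is.na(res$correlations$r)
    corr_ok <- if (require_all) all(cor_sig) else any(cor_sig)

    control_ok <- TRUE
    if (is.finite(shuffled_p) && shuffled_p < alpha) {
      sc <- tuning_correlation(opt_curve$mean_response,
                               shuf[[1L]]$mean_response)
      res$shuffled_r <- sc$r
      res$shuffled_p <- sc$p
      control_ok <- !(sc$p < alpha)
    }
    res$status <- if (corr_ok && control_ok) "gloss_selective" else "not_selective"
  }
  res$is_gloss_selective <- identical(res$status, "gloss_selective")
  if (res$is_gloss_selective)
    res$preference_sign <- preference_sign(opt_curve)
  structure(res, class = "selectivity_result")
}

#' Gloss preference sign of a tuning curve
#'
#' Sign of the Spearman rank correlation between gloss level and the mean
#' response: positive means the unit responds more strongly to glossier
#' stimuli (`"glossy"`), negative to more matte stimuli (`"matte"`); a zero
#' correlation is `"undefined"`.
#'
#' @param curve a `tuning_curve` (normally the optimal shape of a
#'   gloss-selective unit).
#' @return `"glossy"`, `"matte"` or `"undefined"`.
#' @export
preference_sign <- function(curve) {
  gp_check(inherits(curve, "tuning_curve"), "curve must be a tuning_curve")
  if (sd(curve$mean_response) == 0) return("undefined")
  rho <- cor(curve$levels, curve$mean_response, method = "spearman")
  if (is.na(rho) || rho == 0) "undefined" else if (rho > 0) "glossy" else "matte"
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> unit %s: %s (optimal shape %s, preference %s)\n",
              x$unit_id, x$status, x$optimal_shape_id, x$preference_sign))
  invisible(x)
}
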