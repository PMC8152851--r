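# Damped Gauss-Newton least squares for the two-parameter logistic
# y = 1 / (1 + exp(-a (x - b))) on per-level proportions.
#
# Deterministic initializer: b0 by linear interpolation of the 0.5 crossing
# of the proportions (falling back to mean(x)); a0 from the least-squares
# slope of the logit of proportions clipped to [0.01, 0.99]. Levenberg
# damping with step halving guarantees the SSE trace is non-increasing.
#' @noRd
logistic_ls_core <- function(x, p, w = NULL, max_iter = 80L, tol = 1e-12) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  pc <- pmin(pmax(p, 0.01), 0.99)
  z <- qlogis(pc)
  xm <- mean(x)
  a <- sum((x - xm) * (z - mean(z))) / sum((x - xm)^2)
  if (!is.finite(a)) a <- 1e-3
  if (abs(a) < 1e-3) a <- if (a < 0) -1e-3 else 1e-3
  b <- NA_real_
  cr <- which(diff(sign(p - 0.5)) != 0)
  if (length(cr)) {
    i <- cr[1L]
    if (p[i + 1L] != p[i])
      b <- x[i] + (0.5 - p[i]) * (x[i + 1L] - x[i]) / (p[i + 1L] - p[i])
  }
  if (!is.finite(b)) b <- xm

  f <- plogis(a * (x - b))
  r <- p - f
  sse <- sum(w * r * r)
  trace <- sse
  lambda <- 1e-3
  conv <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- f * (1 - f)
    Ja <- g * (x - b)
    Jb <- -a * g
    A11 <- sum(w * Ja * Ja); A12 <- sum(w * Ja * Jb); A22 <- sum(w * Jb * Jb)
    g1 <- sum(w * Ja * r); g2 <- sum(w * Jb * r)
    ok <- FALSE
    for (k in 1:15) {
      d1 <- A11 + lambda * max(A11, 1e-12)
      d2 <- A22 + lambda * max(A22, 1e-12)
      det <- d1 * d2 - A12 * A12
      if (!is.finite(det) || abs(det) < 1e-300) { lambda <- lambda * 10; next }
      a2 <- a + (d2 * g1 - A12 * g2) / det
      b2 <- b + (-A12 * g1 + d1 * g2) / det
      f2 <- plogis(a2 * (x - b2))
      r2 <- p - f2
      sse2 <- sum(w * r2 * r2)
      if (is.finite(sse2) && sse2 <= sse) { ok <- TRUE; break }
      lambda <- lambda * 10
    }
    if (!ok) break
    rel <- (sse - sse2) / max(sse, 1e-300)
    a <- a2; b <- b2; f <- f2; r <- r2; sse <- sse2
    trace <- c(trace, sse)
    lambda <- max(lambda / 10, 1e-10)
    if (rel < tol) { conv <- TRUE; break }
  }
  list(a = a, b = b, sse = sse, converged = (conv || sse < 1e-20) &&
         is.finite(a) && is.finite(b), iterations = it, trace = trace)
}

#' Aggregate binary gloss choices into per-level proportions
#'
#' Averages the "glossier" choices over shapes and illuminations for each
#' gloss level, within groups defined by the stimulation factor or by the
#' muscimol epoch. Middle-level trials (randomly rewarded) contribute their
#' recorded choice like any other trial.
#'
#' @param trials a `behavior_trials` data frame.
#' @param group_by `"stimulation"`, `"timepoint"` or `"none"`.
#' @param levels admissible gloss levels (default 1:7); trials outside this
#'   set are a validation error.
#' @return a data frame of class `choice_table` with columns `group`,
#'   `gloss_level`, `n_trials`, `n_glossier`, `proportion`.
#' @export
aggregate_choice_proportions <- function(trials,
                                         group_by = c("stimulation", "timepoint", "none"),
                                         levels = 1:7) {
  group_by <- match.arg(group_by)
  gp_check(is.data.frame(trials) &&
             all(c("gloss_level", "choice") %in% names(trials)),
           "trials must have gloss_level and choice columns")
  gp_check(all(trials$choice %in% c("glossier", "less_glossy")),
           "choice must be 'glossier' or 'less_glossy'")
  gp_check(all(trials$gloss_level %in% levels),
           sprintf("gloss_level outside %d..%d", min(levels), max(levels)))

  grp <- switch(group_by,
    stimulation = {
      gp_check("stimulation" %in% names(trials), "no stimulation column")
      ifelse(as.logical(trials$stimulation), "stim", "no_stim")
    },
    timepoint = {
      gp_check("timepoint_h" %in% names(trials), "no timepoint_h column")
      tp_key(trials$timepoint_h)
    },
    none = rep("all", nrow(trials))
  )
  y <- as.integer(trials$choice == "glossier")
  agg <- aggregate(cbind(n_trials = rep(1L, nrow(trials)), n_glossier = y),
                   by = list(group = grp, gloss_level = trials$gloss_level),
                   FUN = sum)
  agg <- agg[order(agg$group, agg$gloss_level), ]
  agg$proportion <- agg$n_glossier / agg$n_trials
  rownames(agg) <- NULL
  structure(agg, group_by = group_by,
            class = c("choice_table", "data.frame"))
}

#' Fit the logistic psychometric function
#'
#' Fits `y = 1 / (1 + exp(-a (x - b)))` to per-level choice proportions by
#' least squares (the default, matching fits to plotted proportions), or by
#' trial-level binomial likelihood (`method = "binomial"`, provided for
#' sensitivity checks). `a` is the slope — the sensitivity to a one-level
#' change in glossiness — and `b` the offset, the gloss level of the 50%
#' point. Fits are deterministic: the initializer interpolates the 0.5
#' crossing for `b` and uses the logit-slope for `a`, and the damped
#' Gauss--Newton optimizer has a provably non-increasing objective (the
#' per-iteration SSE trace is returned).
#'
#' @param table a `choice_table` for a single group, or any data frame with
#'   `gloss_level` and `proportion` (plus `n_trials` for weighting or the
#'   binomial method).
#' @param weight_by_n weight levels by trial count (default FALSE: the
#'   canonical session has equal counts, and fits to pooled data stay
#'   comparable with the unweighted convention).
#' @param method `"ls"` (default) or `"binomial"`.
#' @return an object of class `psychometric_fit`: list with `a`, `b`,
#'   `residual_error` (RMS residual in proportion units), `sse`,
#'   `converged`, `n_levels`, `method` and `sse_trace`.
#' @examples
#' x <- 1:7
#' tab <- data.frame(gloss_level = x, proportion = plogis(1.5 * (x - 4)))
#' fit_logistic(tab)
#' @export
fit_logistic <- function(table, weight_by_n = FALSE, method = c("ls", "binomial")) {
  method <- match.arg(method)
  gp_check(is.data.frame(table) && "gloss_level" %in% names(table),
           "table must have a gloss_level column")
  if (!"proportion" %in% names(table) &&
      all(c("n_trials", "n_glossier") %in% names(table)))
    table$proportion <- table$n_glossier / table$n_trials
  gp_check("proportion" %in% names(table), "table must have a proportion column")
  if ("group" %in% names(table))
    gp_check(length(unique(table$group)) == 1L,
             "fit_logistic expects a single group; split the table first")
  ok <- is.finite(table$proportion)
  table <- table[ok, ]
  x <- table$gloss_level
  p <- table$proportion
  gp_check(length(unique(x)) >= 3, "need proportions at >= 3 distinct levels")
  gp_check(all(p >= 0 & p <= 1), "proportions must lie in [0, 1]")

  if (method == "binomial") {
    gp_check(all(c("n_trials", "n_glossier") %in% names(table)),
             "binomial method needs n_trials and n_glossier")
    fit <- suppressWarnings(
      glm(cbind(table$n_glossier, table$n_trials - table$n_glossier) ~ x,
          family = binomial()))
    a <- unname(coef(fit)[2L])
    b <- -unname(coef(fit)[1L]) / a
    pr <- plogis(a * (x - b))
    sse <- sum((p - pr)^2)
    core <- list(a = a, b = b, sse = sse, converged = fit$converged,
                 iterations = fit$iter, trace = sse)
  } else {
    w <- if (isTRUE(weight_by_n) && "n_trials" %in% names(table))
      table$n_trials else NULL
    core <- logistic_ls_core(x, p, w)
  }
  structure(list(a = core$a, b = core$b,
                 residual_error = sqrt(core$sse / length(x)),
                 sse = core$sse, converged = core$converged,
                 n_levels = length(x), method = method,
                 iterations = core$iterations, sse_trace = core$trace),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> a = %.4f, b = %.4f (RMS residual %.4f, %s)\n",
              x$a, x$b, x$residual_error,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Keep-or-exclude decision for a psychometric fit
#'
#' Datasets whose logistic fit is extremely poor are excluded from further
#' analysis. The default rule excludes a fit when its RMS residual strictly
#' exceeds `threshold` (0.25, half the dynamic range of a proportion), when
#' it failed to converge, or when the fitted slope magnitude is degenerate
#' (|a| < `min_slope`, i.e. the curve carries no measurable sensitivity —
#' the limiting fit to level-independent proportions). A residual exactly
#' at the threshold is kept.
#'
#' @param fit a `psychometric_fit`.
#' @param threshold RMS-residual exclusion threshold (default 0.25).
#' @param min_slope degenerate-slope bound (default 1e-3).
#' @return list with `keep` (logical), `reason` (`"ok"`,
#'   `"residual_above_threshold"`, `"not_converged"`,
#'   `"degenerate_slope"`) and the measured `residual_error`.
#' @export
evaluate_fit_quality <- function(fit, threshold = 0.25, min_slope = 1e-3) {
  gp_check(inherits(fit, "psychometric_fit"), "fit must be a psychometric_fit")
  gp_check(is.numeric(threshold) && threshold > 0, "threshold must be positive")
  reason <- if (!isTRUE(fit$converged)) "not_converged"
  else if (fit$residual_error > threshold) "residual_above_threshold"
  else if (abs(fit$a) < min_slope) "degenerate_slope"
  else "ok"
  list(keep = identical(reason, "ok"), reason = reason,
       residual_error = fit$residual_error)
}
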