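#' Build a gloss-level parameter ladder in c--d space
#'
#' Gloss stimuli are parameterized by two perceptual coordinates: `c`, related
#' to the contrast of specular highlights, and `d`, related to their
#' sharpness. A discrimination ladder samples the diagonal of this space at
#' equal intervals: `c` is spaced linearly between `c_min` and `c_max`, and
#' `d` steps along with it so that the ratio of adjacent increments
#' Δc/Δd stays fixed (1.78 in the canonical task, which makes the diagonal
#' perceptually uniform). Only increments of `d` are constrained, so the
#' ladder anchors `d` at a configurable value for level 1.
#'
#' @param c_min,c_max range of the highlight-contrast coordinate `c`
#'   (dimensionless). The canonical ranges are 0.029--0.119 (monkey T) and
#'   0.0215--0.1265 (monkey G).
#' @param n_levels number of gloss levels (default 7).
#' @param cd_ratio fixed ratio Δc/Δd between adjacent increments
#'   (default 1.78).
#' @param d_anchor value of `d` assigned to level 1 (default 0; only
#'   differences in `d` are meaningful).
#' @return an object of class `gloss_ladder`: a list with a `levels`
#'   data frame (`level`, `c`, `d`) and the scalar metadata
#'   `c_min`, `c_max`, `cd_ratio`, `d_anchor`.
#' @examples
#' lad <- build_gloss_ladder(0.029, 0.119)
#' lad$levels
#' @export
build_gloss_ladder <- function(c_min, c_max, n_levels = 7L, cd_ratio = 1.78,
                               d_anchor = 0) {
  for (nm in c("c_min", "c_max", "cd_ratio", "d_anchor")) {
    v <- get(nm)
    gp_check(is.numeric(v) && length(v) == 1L && is.finite(v),
             paste0(nm, " must be a single finite number"))
  }
  gp_check(c_max > c_min, "c_max must be strictly greater than c_min")
  gp_check(is_count(n_levels) && n_levels >= 2, "n_levels must be an integer >= 2")
  gp_check(cd_ratio > 0, "cd_ratio must be positive")
  n_levels <- as.integer(n_levels)

  dc <- (c_max - c_min) / (n_levels - 1L)
  idx <- seq_len(n_levels) - 1L
  cs <- c_min + idx * dc
  cs[n_levels] <- c_max          # endpoints exact by construction
  ds <- d_anchor + idx * (dc / cd_ratio)

  structure(
    list(
      levels = data.frame(level = seq_len(n_levels), c = cs, d = ds),
      c_min = c_min, c_max = c_max, cd_ratio = cd_ratio, d_anchor = d_anchor
    ),
    class = "gloss_ladder"
  )
}

#' @export
print.gloss_ladder <- function(x, ...) {
  cat(sprintf("<gloss_ladder> %d levels, c in [%g, %g], Δc/Δd = %g\n",
              nrow(x$levels), x$c_min, x$c_max, x$cd_ratio))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Generate a seeded family of spherical-harmonics shapes
#'
#' Object shapes for the gloss task are random closed surfaces built from a
#' spherical-harmonics basis: the radius is a weighted sum of harmonics up to
#' `basis_order`, and a new shape family is drawn each daily session by
#' incrementing the session seed. Five complexity levels span smooth
#' ellipsoid-like shapes (all power in harmonic orders <= 2) to bumpy shapes
#' (increasing power in orders > 2). The complexity metric is the total
#' power in harmonics above order 2; the high-order coefficient block of
#' each shape is rescaled so that this power is exactly
#' `(0.15 * (k - 1) / (n_complexity - 1))^2` for complexity level `k`, which
#' makes complexity strictly monotone in `k` irrespective of the random
#' draw. Coefficients are drawn with the Mersenne-Twister generator under a
#' local RNG state, so a given `(session_seed, n_complexity, basis_order)`
#' reproduces the same family byte for byte on any platform.
#'
#' @param session_seed integer >= 0; incremented across daily sessions.
#' @param n_complexity number of complexity levels (default 5).
#' @param basis_order maximum spherical-harmonics order (default 6); each
#'   shape carries `(basis_order + 1)^2` coefficients.
#' @return a list of class `shape_set`; each element is a `shape_spec` list
#'   with `shape_id`, `complexity_level`, `seed`, `basis_order`,
#'   `coefficients` and `complexity_power`.
#' @export
generate_shape_set <- function(session_seed, n_complexity = 5L, basis_order = 6L) {
  gp_check(is.numeric(session_seed) && length(session_seed) == 1L &&
             is.finite(session_seed) && session_seed >= 0 &&
             session_seed == trunc(session_seed),
           "session_seed must be a single integer >= 0")
  gp_check(is_count(n_complexity), "n_complexity must be a positive integer")
  gp_check(is_count(basis_order) && basis_order >= 1,
           "basis_order must be an integer >= 1")
  n_complexity <- as.integer(n_complexity)
  basis_order <- as.integer(basis_order)

  orders <- rep.int(0:basis_order, times = 2L * (0:basis_order) + 1L)
  n_coef <- length(orders)              # (basis_order + 1)^2
  high <- orders > 2L

  shapes <- with_rng(session_seed, {
    lapply(seq_len(n_complexity), function(k) {
      raw <- runif(n_coef, -1, 1)
      coef <- numeric(n_coef)
      # low-order base: mean radius 1 plus mild ellipsoidal perturbation
      coef[!high] <- 0.1 * raw[!high]
      coef[1L] <- 1 + 0.05 * raw[1L]
      amp <- if (n_complexity == 1L) 0 else 0.15 * (k - 1) / (n_complexity - 1)
      if (any(high) && amp > 0) {
        hv <- raw[high]
        nrm <- sqrt(sum(hv^2))
        if (nrm == 0) hv <- rep(1 / sqrt(sum(high)), sum(high)) else hv <- hv / nrm
        coef[high] <- amp * hv
      }
      structure(
        list(
          shape_id = sprintf("s%d_c%d", session_seed, k),
          complexity_level = k,
          seed = as.integer(session_seed),
          basis_order = basis_order,
          coefficients = coef,
          complexity_power = sum(coef[high]^2)
        ),
        class = "shape_spec"
      )
    })
  })
  structure(shapes, class = "shape_set")
}

#' @noRd
as_gloss_levels <- function(ladder) {
  if (inherits(ladder, "gloss_ladder")) return(ladder$levels$level)
  gp_check(is.numeric(ladder) && length(ladder) >= 1 && all(is.finite(ladder)) &&
             anyDuplicated(ladder) == 0,
           "ladder must be a gloss_ladder or a vector of distinct gloss levels")
  as.integer(ladder)
}

#' Shape ids of a shape set
#' @param shapes a `shape_set` or character vector of ids (passed through).
#' @return character vector of shape ids.
#' @export
shape_ids <- function(shapes) {
  if (inherits(shapes, "shape_set")) vapply(shapes, `[[`, "", "shape_id")
  else if (is.character(shapes)) shapes
  else gp_stop("shapes must be a shape_set or a character vector of ids")
}

#' Build the factorial task condition grid
#'
#' Crosses gloss level, object shape, illumination and (optionally) the
#' microstimulation factor into the full factorial trial design. The
#' canonical session crosses 7 gloss levels x 5 shapes x 3 illuminations
#' (105 test stimuli) x 2 stimulation conditions = 210 conditions, each
#' tested once per session. Row order is fixed (gloss level slowest, then
#' shape, then illumination, stimulation fastest) so downstream joins are
#' deterministic.
#'
#' @param ladder a [build_gloss_ladder()] object (or a bare vector of gloss
#'   levels).
#' @param shapes a `shape_set` or character vector of shape ids.
#' @param illuminations character vector of illumination ids (default the
#'   three high-dynamic-range environments Eucalyptus, Campus, Building).
#' @param include_stimulation_factor cross with stimulation on/off?
#' @return a data frame of class `condition_grid` with columns
#'   `gloss_level`, `shape_id`, `illumination_id`, `stimulation`, and the
#'   factor sets stored in attribute `factors`.
#' @export
build_condition_grid <- function(ladder, shapes,
                                 illuminations = c("Eucalyptus", "Campus", "Building"),
                                 include_stimulation_factor = TRUE) {
  levels <- as_gloss_levels(ladder)
  sid <- shape_ids(shapes)
  gp_check(length(sid) > 0, "shapes must be non-empty")
  gp_check(anyDuplicated(sid) == 0, "shape ids must be unique")
  gp_check(is.character(illuminations) && length(illuminations) > 0,
           "illuminations must be a non-empty character vector")
  gp_check(anyDuplicated(illuminations) == 0, "illumination ids must be unique")

  stim_set <- if (isTRUE(include_stimulation_factor)) c(FALSE, TRUE) else FALSE
  # expand.grid varies the first factor fastest; list fastest-changing first
  g <- expand.grid(stimulation = stim_set,
                   illumination_id = illuminations,
                   shape_id = sid,
                   gloss_level = levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("gloss_level", "shape_id", "illumination_id", "stimulation")]
  rownames(g) <- NULL
  structure(g,
            factors = list(gloss_level = levels,
                           shape_id = sid,
                           illumination_id = illuminations,
                           stimulation = stim_set),
            class = c("condition_grid", "data.frame"))
}

#' Build the gloss-selectivity stimulus set (object + shuffled images)
#'
#' The selectivity screen presents every shape at every gloss level in a
#' single illumination (canonically 5 x 7 = 35 object images), plus one
#' pixel-shuffled image per gloss level of one designated shape (the optimal
#' shape, 7 shuffled images). Shuffled images preserve the luminance
#' histogram inside the object contour while destroying gloss structure;
#' they are represented here as flagged stimulus specs, not pixel arrays.
#'
#' @param ladder a [build_gloss_ladder()] object.
#' @param shapes `shape_set` or character vector of shape ids.
#' @param illumination single illumination id (default "Eucalyptus").
#' @param shuffled_shape_id id of the shape whose shuffled versions are
#'   included; must be one of `shapes`.
#' @return a data frame of class `selectivity_set` with columns
#'   `gloss_level`, `shape_id`, `illumination_id`, `shuffled`.
#' @export
build_selectivity_stimulus_set <- function(ladder, shapes,
                                           illumination = "Eucalyptus",
                                           shuffled_shape_id) {
  lv <- as_gloss_levels(ladder)
  sid <- shape_ids(shapes)
  gp_check(is.character(illumination) && length(illumination) == 1L,
           "illumination must be a single id")
  gp_check(is.character(shuffled_shape_id) && length(shuffled_shape_id) == 1L &&
             shuffled_shape_id %in% sid,
           "shuffled_shape_id must be one of the supplied shape ids")

  obj <- expand.grid(shape_id = sid, gloss_level = lv,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  obj <- obj[, c("gloss_level", "shape_id")]
  obj$illumination_id <- illumination
  obj$shuffled <- FALSE
  shuf <- data.frame(gloss_level = lv, shape_id = shuffled_shape_id,
                     illumination_id = illumination, shuffled = TRUE,
                     stringsAsFactors = FALSE)
  out <- rbind(obj, shuf)
  rownames(out) <- NULL
  structure(out,
            factors = list(gloss_level = lv, shape_id = sid,
                           illumination_id = illumination,
                           shuffled_shape_id = shuffled_shape_id),
            class = c("selectivity_set", "data.frame"))
}
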