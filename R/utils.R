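#' @noRd
gp_stop <- function(msg, class = "glossperm_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "glossperm_error")))
}

#' @noRd
gp_check <- function(ok, msg, class = "glossperm_validation_error") {
  if (!isTRUE(ok)) gp_stop(msg, class = class)
  invisible(TRUE)
}

#' Evaluate an expression under a local, portable RNG state
#'
#' Seeds the Mersenne-Twister generator (with Inversion normal sampling and
#' Rejection discrete sampling, i.e. the modern R defaults) for the duration
#' of `code` and restores the caller's RNG state afterwards, so simulations
#' are reproducible without clobbering the global stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_rng <- function(seed, code) {
  gp_check(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
           "seed must be a single finite number")
  gp_check(abs(seed) < 2^31, "seed must be below 2^31 (32-bit integer)")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Derive a schedule of sub-seeds from one master seed
#'
#' Draws `n` distinct 32-bit-safe integer seeds under [with_rng()], so each
#' stochastic pipeline stage gets its own reproducible stream.
#'
#' @param seed master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
seed_schedule <- function(seed, n) {
  with_rng(seed, sample.int(2147483646L, n))
}

# Per-element character key for a time point in hours ("0", "0.5", "18").
#' @noRd
tp_key <- function(tp) {
  vapply(tp, function(t) format(t, trim = TRUE, scientific = FALSE), "")
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only for config provenance columns; not cryptographic. Arithmetic is
# done in doubles with a 16-bit split so products never exceed 2^53.
#' @noRd
fnv1a32 <- function(x) {
  mul32 <- function(a, b) {
    al <- a %% 65536
    ah <- (a - al) / 65536
    (((ah * b) %% 65536) * 65536 + al * b) %% 4294967296
  }
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
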