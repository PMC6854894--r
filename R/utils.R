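#' Round half away from zero
#'
#' Printed-style integer percentages in diagnostic reports use
#' conventional half-up rounding (0.5 rounds up), not the banker's
#' rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All randomness in the package flows from one master seed; independent
#' modules draw from streams keyed by a short string tag so that, e.g.,
#' plate simulation and cohort simulation can be tested independently
#' without sharing RNG state.
#'
#' @param seed master seed (integer).
#' @param tag character scalar naming the stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(as.integer(charToRaw(tag)) * seq_along(charToRaw(tag))^2)
  if (length(h) == 0L) h <- 0
  ((abs(as.double(seed)) %% 2147483647) * 69069 + h * 30011 + 1) %% 2147483646
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used across constructors
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lo = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lo || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %s", name, format(lo)),
         call. = FALSE)
  invisible(as.integer(x))
}

#' Exact Clopper-Pearson interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

#' Wilson score interval for a binomial proportion
#'
#' @inheritParams clopper_pearson
#' @return named numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  # continuity-correction warning is irrelevant: only conf.int is used
  ci <- suppressWarnings(
    stats::prop.test(x, n, conf.level = conf, correct = FALSE))$conf.int
  c(lower = ci[1L], upper = ci[2L])
}
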