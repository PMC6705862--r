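#' Approximate-entropy parameters
#'
#' Settings for [apen()] / [normalized_apen()] on the ball-speed series:
#' embedding (vector) length `m = 2` and tolerance `r = 0.2` standard
#' deviations of the series, the conventional inputs for regularity analysis
#' of short physiological and behavioural series. Series shorter than
#' `min_length` frames (default 200, i.e. 8 s at 25 Hz) are refused unless
#' explicitly overridden, because ApEn estimates destabilize on very short
#' records.
#'
#' @param m embedding length; default 2.
#' @param r_factor tolerance as a multiple of the series SD; default 0.2.
#' @param min_length minimum series length in samples; default 200.
#' @param shuffles surrogate count for the shuffle-normalized mode of
#'   [normalized_apen()]; 0 (default) selects the amplitude-normalized mode.
#' @param seed integer seed for surrogate shuffling.
#' @return An object of class `apen_params`.
#' @export
apen_params <- function(m = 2, r_factor = 0.2, min_length = 200,
                        shuffles = 0, seed = 1L) {
  stopifnot(is_count(m), m >= 1, is_scalar_num(r_factor), r_factor > 0,
            is_count(min_length), min_length > m + 1, is_count(shuffles))
  structure(list(m = as.integer(m), r_factor = r_factor,
                 min_length = as.integer(min_length),
                 shuffles = as.integer(shuffles), seed = as.integer(seed)),
            class = "apen_params")
}

# Phi_k: mean over templates of log of the fraction of templates (self
# included) within Chebyshev distance r.
apen_phi <- function(x, k, r) {
  n <- length(x)
  N <- n - k + 1L
  # Chebyshev distance built dimension by dimension as a running maximum
  d <- matrix(0, N, N)
  for (j in seq_len(k)) {
    v <- x[j:(j + N - 1L)]
    d <- pmax(d, abs(outer(v, v, "-")))
  }
  C <- rowSums(d <= r) / N
  mean(log(C))
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r) = Phi_m - Phi_{m+1}` with self-matches included and Chebyshev
#' distance between embedded template vectors; `r = r_factor * sd(x)`. Lower
#' values mean a more regular, repeatable, predictable series. A constant
#' series returns exactly 0 (with `r = 0`, every distance `0 <= 0` matches).
#' Because the tolerance scales with the series SD, the statistic is
#' invariant to affine transforms of the series.
#'
#' @param x numeric series (here: ball speed per frame transition).
#' @param params an [apen_params()].
#' @param allow_short bypass the `min_length` reliability rule (used for
#'   short diagnostic series).
#' @return Scalar approximate entropy (arbitrary units).
#' @export
apen <- function(x, params = apen_params(), allow_short = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  m <- params$m
  if (n <= m + 1L) stop_usage("series too short for ApEn with m = ", m)
  if (n < params$min_length && !allow_short)
    stop_usage("series length ", n, " below min_length ", params$min_length,
               " (set allow_short = TRUE to override)")
  s <- stats::sd(x)
  # numerically constant series: every template matches, ApEn is exactly 0
  if (s <= 1e-10 * (max(abs(x)) + 1)) return(0)
  r <- params$r_factor * s
  apen_phi(x, m, r) - apen_phi(x, m + 1L, r)
}

#' Normalized approximate entropy
#'
#' ApEn made comparable across possessions of different lengths and scales,
#' with output in `[0, 2]` (arbitrary units). Two modes:
#'
#' * amplitude-normalized (default, `shuffles = 0`): ApEn of the z-scored
#'   series. Since the tolerance already scales with the series SD, this
#'   equals plain [apen()] up to floating error (asserted internally); the
#'   mode exists to make the normalization explicit in reports.
#' * shuffle-surrogate (`shuffles > 0`): the series' ApEn divided by the mean
#'   ApEn of `shuffles` random permutations, rescaled by 2 so a structureless
#'   series sits near the top of the `[0, 2]` range. Seeded via
#'   `params$seed`; clipped into `[0, 2]` with a warning if needed.
#'
#' @inheritParams apen
#' @return Scalar in `[0, 2]`.
#' @export
normalized_apen <- function(x, params = apen_params(), allow_short = FALSE) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (is.na(s)) stop_usage("series too short for ApEn")
  if (s <= 1e-10 * (max(abs(x)) + 1)) {
    if (length(x) <= params$m + 1L) stop_usage("series too short for ApEn")
    if (length(x) < params$min_length && !allow_short)
      stop_usage("series length below min_length (set allow_short = TRUE)")
    return(0)
  }
  if (params$shuffles == 0L) {
    z <- (x - mean(x)) / s
    a <- apen(z, params, allow_short)
    a0 <- apen(x, params, allow_short)
    if (abs(a - a0) > 1e-8)
      warning("amplitude normalization changed ApEn by ", abs(a - a0))
    return(min(max(a, 0), 2))
  }
  a <- apen(x, params, allow_short)
  surr <- with_seed(params$seed, {
    vapply(seq_len(params$shuffles),
           function(i) apen(sample(x), params, allow_short), numeric(1))
  })
  v <- 2 * a / mean(surr)
  if (v > 2 || v < 0) {
    warning("normalized ApEn clipped into [0, 2]")
    v <- min(max(v, 0), 2)
  }
  v
}
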