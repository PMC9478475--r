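#' Hertz to Bark conversion
#'
#' Traunmueller's rational approximation of the Bark critical-band scale:
#' `z = 26.81 f / (1960 + f) - 0.53`.
#'
#' @param f frequency in Hz (vectorized, must be non-negative).
#' @return Bark values.
#' @examples
#' hz_to_bark(c(0, 500, 1000))
#' @export
hz_to_bark <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) stop("frequencies must be finite and >= 0")
  26.81 * f / (1960 + f) - 0.53
}

#' First DCT coefficients of a trajectory
#'
#' Linearly resamples a trajectory to `n_resample` uniform points and returns
#' its first `n_coef` DCT-II coefficients, scaled so that `c0` equals the
#' arithmetic mean of the resampled trajectory, `c1` its tilt (half-cosine
#' loading) and `c2` its curvature. Computed by the even-symmetric FFT
#' factorization of the DCT-II.
#'
#' @param track numeric trajectory (length >= 3), e.g. a Bark-scaled formant.
#' @param n_coef number of coefficients returned.
#' @param n_resample fixed resampling length applied before the transform so
#'   coefficients are comparable across durations.
#' @return named numeric vector `c0 ... c(n_coef-1)`.
#' @export
dct_coefficients <- function(track, n_coef = 3L, n_resample = 20L) {
  if (length(track) < 3L) stop("track must have at least 3 samples")
  if (any(!is.finite(track))) stop("track contains non-finite values")
  n_coef <- stopifnot_scalar_count(n_coef, "n_coef")
  n_resample <- stopifnot_scalar_count(n_resample, "n_resample", min = 3L)
  x <- approx(seq_along(track), track, n = n_resample)$y
  N <- length(x)
  # DCT-II via FFT of the even-odd reordered sequence
  v <- c(x[seq(1L, N, by = 2L)], rev(x[seq(2L, N, by = 2L)]))
  V <- fft(v)
  k <- 0:(N - 1L)
  s <- Re(V * exp(-1i * pi * k / (2 * N)))
  coef <- s / N
  coef[-1L] <- 2 * coef[-1L]
  setNames(coef[seq_len(n_coef)], paste0("c", seq_len(n_coef) - 1L))
}

#' Assemble the 7-D feature vector of a word token
#'
#' Converts a token's F1/F2 trajectories to Bark, takes the first three DCT
#' coefficients of each (mean, slope, curvature), and appends duration.
#'
#' @param token a `vowel_token` (or any list with `f1_track`, `f2_track`,
#'   `duration`, plus identifiers).
#' @param n_resample resampling length for the DCT.
#' @return one-row data frame: `talker_id`, `word_id`, `pair_id`, `f1_c0`,
#'   `f1_c1`, `f1_c2`, `f2_c0`, `f2_c1`, `f2_c2`, `duration`.
#' @export
featurize <- function(token, n_resample = 20L) {
  if (is.null(token$f1_track) || is.null(token$f2_track)) {
    stop("token has no formant tracks; synthesize them or run measure_formants()")
  }
  b1 <- dct_coefficients(hz_to_bark(token$f1_track), 3L, n_resample)
  b2 <- dct_coefficients(hz_to_bark(token$f2_track), 3L, n_resample)
  data.frame(talker_id = token$talker_id %||% NA_character_,
             word_id = token$word_id %||% NA_character_,
             pair_id = token$pair_id %||% NA_character_,
             f1_c0 = b1[[1]], f1_c1 = b1[[2]], f1_c2 = b1[[3]],
             f2_c0 = b2[[1]], f2_c1 = b2[[2]], f2_c2 = b2[[3]],
             duration = token$duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-word feature table for a token set
#'
#' Featurizes every token and averages coefficient-wise across repetitions,
#' yielding one 7-D vector per talker-by-word.
#'
#' @param tokens list of `vowel_token`s.
#' @param n_resample resampling length for the DCT.
#' @return data frame, one row per talker x word.
#' @export
feature_table <- function(tokens, n_resample = 20L) {
  rows <- do.call(rbind, lapply(tokens, featurize, n_resample = n_resample))
  num <- c("f1_c0", "f1_c1", "f1_c2", "f2_c0", "f2_c1", "f2_c2", "duration")
  agg <- aggregate(rows[num],
                   by = rows[c("talker_id", "word_id", "pair_id")], mean)
  agg[order(agg$talker_id, agg$word_id), c("talker_id", "word_id", "pair_id", num)]
}
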