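#' Autocorrelation f0 estimate
#'
#' Median f0 over voiced analysis frames (normalized autocorrelation peak
#' search within the given pitch range).
#'
#' @param audio mono waveform.
#' @param fs sample rate.
#' @param f0_range search range in Hz.
#' @param frame_len analysis frame in seconds.
#' @return median f0 in Hz.
#' @export
estimate_f0 <- function(audio, fs, f0_range = c(60, 400), frame_len = 0.04) {
  x <- as.numeric(audio)
  wl <- round(frame_len * fs)
  if (length(x) < wl) wl <- length(x)
  lag_min <- max(2L, floor(fs / f0_range[2]))
  lag_max <- min(wl - 1L, ceiling(fs / f0_range[1]))
  if (lag_max <= lag_min) stop("audio too short for the pitch range")
  starts <- seq(1L, max(1L, length(x) - wl + 1L), by = max(1L, wl %/% 2L))
  f0s <- vapply(starts, function(s) {
    fr <- x[s:(s + wl - 1L)]
    fr <- fr - mean(fr)
    e0 <- sum(fr^2)
    if (e0 <= 0) return(NA_real_)
    ac <- vapply(lag_min:lag_max, function(l) {
      a <- fr[seq_len(wl - l)]; b <- fr[(l + 1L):wl]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2) + 1e-12)
    }, numeric(1))
    mx <- max(ac)
    if (mx < 0.3) return(NA_real_)
    pk <- which(ac >= 0.9 * mx)[1]   # smallest qualifying lag avoids octave errors
    fs / (lag_min + pk - 1L)
  }, numeric(1))
  f0s <- f0s[is.finite(f0s)]
  if (!length(f0s)) stop("no voiced frames found")
  median(f0s)
}

# glottal epoch marks: peaks of the zero-phase low-passed fundamental, so
# successive grains stay phase-coherent cycle to cycle
pitch_marks <- function(x, fs, f0) {
  period <- fs / f0
  n <- length(x)
  wc <- min(0.95, 1.5 * f0 / (fs / 2))
  ref <- tryCatch(
    as.numeric(signal::filtfilt(signal::butter(2, wc, "low"), x)),
    error = function(e) x)
  first <- which.max(ref[seq_len(min(n, ceiling(1.5 * period)))])
  marks <- first
  repeat {
    nxt <- marks[length(marks)] + period
    lo <- round(nxt - 0.3 * period); hi <- round(nxt + 0.3 * period)
    if (hi > n) break
    lo <- max(lo, marks[length(marks)] + 1)
    w <- lo:hi
    marks <- c(marks, w[which.max(ref[w])])
  }
  marks
}

#' Time-domain pitch-synchronous overlap-add modification
#'
#' TD-PSOLA: Hann-windowed two-period grains centered on glottal epoch marks
#' are re-laid at a new epoch spacing, changing f0 by `pitch_factor` and
#' duration by `time_factor` independently.
#'
#' @param audio mono waveform (voiced).
#' @param fs sample rate.
#' @param time_factor output duration / input duration.
#' @param pitch_factor output f0 / input f0.
#' @param f0 input f0 (Hz); estimated when `NULL`.
#' @return modified waveform.
#' @export
psola <- function(audio, fs, time_factor = 1, pitch_factor = 1, f0 = NULL) {
  stopifnot(time_factor > 0, pitch_factor > 0)
  x <- as.numeric(audio)
  if (is.null(f0)) f0 <- estimate_f0(x, fs)
  marks <- pitch_marks(x, fs, f0)
  n_in <- length(x)
  n_out <- round(n_in * time_factor)
  t_in <- fs / f0                    # input period, samples
  t_out <- t_in / pitch_factor       # output epoch spacing
  out <- numeric(n_out)
  wsum <- numeric(n_out)
  pos <- marks[1] * time_factor
  while (pos <= n_out) {
    src_center <- pos / time_factor
    m <- marks[which.min(abs(marks - src_center))]
    half <- round(t_in)
    lo <- m - half; hi <- m + half
    if (lo >= 1 && hi <= n_in) {
      grain <- x[lo:hi]
      win <- 0.5 - 0.5 * cos(2 * pi * seq_along(grain) / (length(grain) + 1))
      gi <- round(pos) + (-half):half
      ok <- gi >= 1 & gi <= n_out
      out[gi[ok]] <- out[gi[ok]] + grain[ok] * win[ok]
      wsum[gi[ok]] <- wsum[gi[ok]] + win[ok]
    }
    pos <- pos + t_out
  }
  nz <- wsum > 1e-3
  out[nz] <- out[nz] / wsum[nz]
  out
}

#' Vocal disguise specification
#'
#' Multiplicative lowering factors for f0 and formant frequencies, as used to
#' make female voices male-like while preserving intelligibility. Defaults
#' are the mean factors of the reference manipulation (0.62 for f0, 0.81 for
#' formants).
#'
#' @param f0_factor,formant_factor factors in (0, 1].
#' @param talker_id optional identifier.
#' @return a `disguise_spec` list.
#' @export
disguise_spec <- function(f0_factor = 0.62, formant_factor = 0.81,
                          talker_id = NULL) {
  if (f0_factor <= 0 || f0_factor > 1 || formant_factor <= 0 || formant_factor > 1) {
    stop("disguise factors must lie in (0, 1]")
  }
  structure(list(talker_id = talker_id, f0_factor = f0_factor,
                 formant_factor = formant_factor), class = "disguise_spec")
}

#' Apply a vocal disguise
#'
#' Two paths. Parametric (`vowel_token` input): the token is re-synthesized
#' with its f0 contour scaled by `f0_factor` and its formant trajectories by
#' `formant_factor` — exact by construction. DSP (waveform input): formants
#' are scaled by playback-rate resampling at the formant factor, and duration
#' and f0 are then restored/adjusted by TD-PSOLA; output duration stays
#' within 2% of the input.
#'
#' @param x a `vowel_token` (with or without audio) or a numeric waveform.
#' @param spec a [disguise_spec()].
#' @param fs sample rate; required for waveform input.
#' @return disguised object of the same kind as `x` (tokens get re-synthesized
#'   audio when they carried audio or `with_audio` is TRUE).
#' @param with_audio for token input: synthesize audio of the disguised token.
#' @export
disguise <- function(x, spec = disguise_spec(), fs = NULL, with_audio = NULL) {
  stopifnot(inherits(spec, "disguise_spec"))
  if (inherits(x, "vowel_token")) {
    out <- x
    out$f0_track <- x$f0_track * spec$f0_factor
    out$f1_track <- x$f1_track * spec$formant_factor
    out$f2_track <- x$f2_track * spec$formant_factor
    want_audio <- if (is.null(with_audio)) !is.null(x$audio) else with_audio
    if (want_audio) {
      out$audio <- synthesize_vowel_audio(out$f1_track, out$f2_track,
                                          out$f0_track, out$duration,
                                          fs = x$fs,
                                          f3 = 2800 * spec$formant_factor)
    }
    return(out)
  }
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("fs is required for waveform input")
  disguise_audio(as.numeric(x), fs, spec)
}

# DSP path: spectral compression by resampling, then pitch correction by
# LP-PSOLA — the overlap-add runs on the LPC excitation residual (flat
# spectrum, so re-spacing the pulses cannot distort formants) and the
# measured time-varying formant envelope is re-applied afterwards.
disguise_audio <- function(x, fs, spec, f3 = 2800,
                           bandwidths = c(80, 90, 140)) {
  a <- spec$formant_factor
  b <- spec$f0_factor
  if (a == 1 && b == 1) return(structure(as.numeric(x), fs = fs))
  n <- length(x)
  # play slower by 1/a: all frequencies (formants and f0) scale by a
  idx <- seq(1, n, by = a)
  y <- approx(seq_len(n), x, xout = idx)$y
  f0_in <- estimate_f0(x, fs)
  bw <- bandwidths * a
  env <- tryCatch({
    trk <- measure_formants(y, fs, ceiling = min(8000, max(4000, 5500 * a)))
    tt <- seq(0, 1, length.out = length(y))
    grid <- seq(0, 1, length.out = nrow(trk))
    cbind(approx(grid, trk$f1, tt)$y, approx(grid, trk$f2, tt)$y,
          rep(f3 * a, length(y)))
  }, error = function(e) NULL)
  if (is.null(env)) {
    # unvoiced/untrackable input: plain waveform PSOLA
    out <- psola(y, fs, time_factor = a, pitch_factor = b / a, f0 = f0_in * a)
    return(structure(out, fs = fs))
  }
  resid <- .deresonate_cascade(y, env, bw, fs)
  out_r <- psola(resid, fs, time_factor = a, pitch_factor = b / a,
                 f0 = f0_in * a)
  tt_out <- seq(0, 1, length.out = length(out_r))
  grid_in <- seq(0, 1, length.out = length(y))
  env_out <- cbind(approx(grid_in, env[, 1], tt_out)$y,
                   approx(grid_in, env[, 2], tt_out)$y,
                   rep(f3 * a, length(out_r)))
  out <- .resonate_cascade(out_r, env_out, bw, fs)
  structure(out, fs = fs)
}
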