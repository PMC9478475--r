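#' RMS-normalize audio to a target level
#'
#' Scales the waveform so its RMS amplitude equals the target sound pressure
#' level in the Praat convention: full scale = 1 Pa against the 2e-5 Pa
#' reference, i.e. target RMS `= 2e-5 * 10^(target_rms_db / 20)` (about
#' 0.035566 at 65 dB).
#'
#' @param audio waveform.
#' @param target_rms_db target level in dB SPL.
#' @return scaled waveform (attributes preserved).
#' @export
rms_normalize <- function(audio, target_rms_db = 65) {
  r <- rms(as.numeric(audio))
  if (!is.finite(r) || r == 0) stop("cannot normalize silent audio")
  target <- 2e-5 * 10^(target_rms_db / 20)
  out <- audio * (target / r)
  attributes(out) <- attributes(audio)
  out
}

#' Mix a signal with noise at a target SNR
#'
#' Scales the leading noise segment so that
#' `20*log10(rms(signal)/rms(noise)) = snr_db`, then sums. The result carries
#' a logical `clipped` attribute flagging samples beyond full scale.
#'
#' @param signal target waveform.
#' @param noise masker waveform, at least as long as `signal`.
#' @param snr_db target signal-to-noise ratio in dB.
#' @return mixed waveform with a `noise_gain` and `clipped` attribute.
#' @export
mix_at_snr <- function(signal, noise, snr_db = 5) {
  signal <- as.numeric(signal); noise <- as.numeric(noise)
  if (length(noise) < length(signal)) stop("noise must be at least as long as the signal")
  nseg <- noise[seq_along(signal)]
  rs <- rms(signal); rn <- rms(nseg)
  if (rs == 0 || rn == 0) stop("signal and noise must be non-silent")
  gain <- (rs / rn) * 10^(-snr_db / 20)
  out <- signal + gain * nseg
  structure(out, noise_gain = gain, clipped = any(abs(out) > 1))
}

#' Generate speech-shaped noise from a corpus
#'
#' Gaussian noise spectrally shaped so its long-term average spectrum matches
#' the Welch-estimated LTAS of the concatenated corpus: white noise is
#' transformed to the frequency domain and multiplied by the square root of
#' the corpus power spectrum. Deterministic under `seed`. The output is
#' scaled to the corpus RMS.
#'
#' @param corpus list of waveforms (or a single waveform) at `fs`.
#' @param duration output duration in seconds.
#' @param fs sample rate (Hz).
#' @param seed RNG seed.
#' @param n_fft Welch segment length.
#' @return noise waveform of `round(duration * fs)` samples, `fs` attribute set.
#' @export
speech_shaped_noise <- function(corpus, duration, fs = 44100, seed = 1,
                                n_fft = 1024) {
  if (is.numeric(corpus)) corpus <- list(corpus)
  if (!length(corpus)) stop("empty corpus")
  x <- unlist(lapply(corpus, as.numeric))
  if (length(x) < fs) stop("corpus must total at least 1 s of audio")
  psd <- welch_psd(x, n_fft)
  n <- round(duration * fs)
  freqs_psd <- seq(0, fs / 2, length.out = length(psd))
  with_seed(seed, {
    w <- rnorm(n)
    W <- fft(w)
    nh <- n %/% 2L
    f_half <- (0:nh) * fs / n
    env_half <- sqrt(approx(freqs_psd, psd, xout = f_half, rule = 2)$y)
    env <- c(env_half, rev(env_half[2:(n - nh)]))
    y <- Re(fft(W * env, inverse = TRUE)) / n
    y <- y / rms(y) * rms(x)
    structure(y, fs = fs)
  })
}

# Welch power spectral density (Hann window, 50% overlap), one-sided
welch_psd <- function(x, n_fft = 1024) {
  n <- length(x)
  if (n < n_fft) stop("signal shorter than one analysis segment")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_fft) / (n_fft + 1))
  starts <- seq(1L, n - n_fft + 1L, by = n_fft %/% 2L)
  acc <- numeric(n_fft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + n_fft - 1L)] * win
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_len(n_fft %/% 2L + 1L)]
  }
  acc / length(starts) / sum(win^2)
}

#' Long-term average spectrum in dB
#'
#' Welch-estimated one-sided LTAS, for checking the spectral match of
#' generated noise against its source corpus.
#'
#' @param audio waveform.
#' @param fs sample rate.
#' @param n_fft Welch segment length.
#' @param smooth_bins width (bins) of a moving average applied to the power
#'   spectrum before conversion to dB; band-averaging at a few hundred Hz
#'   (e.g. 9 bins at the defaults) compares spectral envelopes rather than
#'   harmonic fine structure.
#' @return data frame with `freq` (Hz) and `level_db` (dB, arbitrary reference).
#' @export
ltas <- function(audio, fs = 44100, n_fft = 1024, smooth_bins = 1L) {
  p <- welch_psd(as.numeric(audio), n_fft)
  if (smooth_bins > 1L) {
    h <- smooth_bins %/% 2L
    cs <- cumsum(c(0, p))
    lo <- pmax(seq_along(p) - h, 1L)
    hi <- pmin(seq_along(p) + h, length(p))
    p <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)   # shrinking window at edges
  }
  data.frame(freq = seq(0, fs / 2, length.out = length(p)),
             level_db = 10 * log10(pmax(p, 1e-30)))
}
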