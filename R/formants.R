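#' Estimate F1/F2 trajectories by LPC analysis
#'
#' Resamples the audio to twice the analysis ceiling, pre-emphasizes, and
#' runs autocorrelation LPC in short Hamming-windowed frames. Formants are
#' the angles of the complex LPC-polynomial roots whose bandwidth falls below
#' a threshold, sorted ascending; frames yielding fewer than two valid
#' formants are interpolated from their neighbors.
#'
#' @param audio mono waveform.
#' @param fs sample rate of `audio` (Hz).
#' @param ceiling analysis ceiling in Hz (highest expected formant; must lie
#'   in 4000-8000 Hz; 5500 suits adult female speech).
#' @param frame_step analysis step in seconds.
#' @param window_len analysis window length in seconds.
#' @param lpc_order LPC model order; default `2 + 2 * floor(ceiling / 1100)`
#'   (two poles per expected formant plus spectral-tilt poles).
#' @param pre_emphasis first-order pre-emphasis coefficient.
#' @param bw_threshold maximum accepted formant bandwidth (Hz).
#' @param smooth window (frames) of the running-median + moving-average
#'   smoother applied to each track; 0 disables smoothing.
#' @return a `formant_track` data frame: `time` (s), `f1`, `f2` (Hz), with
#'   the ceiling as an attribute.
#' @export
measure_formants <- function(audio, fs = 44100, ceiling = 5500,
                             frame_step = 0.002, window_len = 0.025,
                             lpc_order = NULL, pre_emphasis = 0.97,
                             bw_threshold = 400, smooth = 11L) {
  if (!length(audio) || all(audio == 0)) stop("audio is empty or silent")
  if (ceiling < 4000 || ceiling > 8000) stop("ceiling must lie in [4000, 8000] Hz")
  if (is.null(lpc_order)) lpc_order <- 2L + 2L * floor(ceiling / 1100)
  fs_a <- 2 * ceiling
  x <- resample_audio(audio, fs, fs_a)
  x <- c(x[1], x[-1] - pre_emphasis * x[-length(x)])
  wl <- max(32L, round(window_len * fs_a))
  step <- max(1L, round(frame_step * fs_a))
  centers <- seq(1L + wl %/% 2L, length(x) - wl %/% 2L, by = step)
  if (!length(centers)) stop("audio too short for the analysis window")
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(wl) / (wl + 1))
  est <- vapply(centers, function(c0) {
    fr <- x[(c0 - wl %/% 2L):(c0 + wl %/% 2L)][seq_len(wl)] * win
    lpc_formants(fr, fs_a, lpc_order, bw_threshold, ceiling)
  }, numeric(2))
  tms <- (centers - 1) / fs_a
  f1 <- fill_gaps(est[1, ], tms)
  f2 <- fill_gaps(est[2, ], tms)
  if (anyNA(f1) || anyNA(f2)) stop("no frame yielded two formants; cannot track")
  if (smooth > 1L && length(f1) > smooth) {
    f1 <- smooth_track(f1, smooth)
    f2 <- smooth_track(f2, smooth)
  }
  structure(data.frame(time = tms, f1 = f1, f2 = f2),
            ceiling = ceiling, class = c("formant_track", "data.frame"))
}

# F1/F2 of one windowed frame; NA when fewer than two valid roots
lpc_formants <- function(frame, fs, order, bw_threshold, ceiling) {
  r <- autocorr(frame, order)
  if (r[1] <= 0) return(c(NA_real_, NA_real_))
  a <- tryCatch(solve(toeplitz(r[seq_len(order)]), r[2:(order + 1L)]),
                error = function(e) NULL)
  if (is.null(a)) return(c(NA_real_, NA_real_))
  rts <- polyroot(rev(c(1, -a)))          # roots of z^p - a1 z^(p-1) - ...
  ang <- Arg(rts)
  keep <- ang > 0
  f <- ang[keep] * fs / (2 * pi)
  bw <- -log(pmin(Mod(rts[keep]), 0.9999999)) * fs / pi
  ok <- f > 90 & f < ceiling - 50 & bw < bw_threshold
  f <- sort(f[ok])
  if (length(f) < 2L) return(c(NA_real_, NA_real_))
  f[1:2]
}

autocorr <- function(x, order) {
  n <- length(x)
  vapply(0:order, function(k) sum(x[seq_len(n - k)] * x[(k + 1L):n]), numeric(1))
}

# running median (outlier rejection) followed by a moving average with
# shrinking windows at the edges
smooth_track <- function(v, k) {
  k <- k - (1L - k %% 2L)          # force odd
  vm <- stats::runmed(v, k, endrule = "median")
  h <- k %/% 2L
  cs <- cumsum(c(0, vm))
  lo <- pmax(seq_along(vm) - h, 1L)
  hi <- pmin(seq_along(vm) + h, length(vm))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

fill_gaps <- function(v, t) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  if (all(bad)) return(v)
  approx(t[!bad], v[!bad], xout = t, rule = 2)$y
}

# rational-ratio resampling (anti-aliased via signal's polyphase filter)
resample_audio <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(as.numeric(x))
  g <- gcd(round(fs_in), round(fs_out))
  p <- round(fs_out) / g
  q <- round(fs_in) / g
  as.numeric(signal::resample(as.numeric(x), p, q))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
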