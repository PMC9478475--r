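# Canonical nucleus targets for the vowel synthesizer: formant onsets/offsets
# (Hz, adult female) and typical durations (s). Long/short pairs realize the
# Cantonese length contrasts; o/ou and ai/ei the quality contrasts.
NUCLEUS_TARGETS <- list(
  ai  = c(f1_on = 750, f1_off = 400, f2_on = 1300, f2_off = 2100, dur = 0.20),
  aai = c(f1_on = 850, f1_off = 450, f2_on = 1350, f2_off = 2000, dur = 0.32),
  ei  = c(f1_on = 450, f1_off = 380, f2_on = 2000, f2_off = 2300, dur = 0.22),
  o   = c(f1_on = 600, f1_off = 580, f2_on = 950,  f2_off = 900,  dur = 0.25),
  ou  = c(f1_on = 550, f1_off = 420, f2_on = 1000, f2_off = 800,  dur = 0.25),
  au  = c(f1_on = 750, f1_off = 450, f2_on = 1200, f2_off = 900,  dur = 0.20),
  aau = c(f1_on = 850, f1_off = 500, f2_on = 1300, f2_off = 950,  dur = 0.32),
  a   = c(f1_on = 780, f1_off = 760, f2_on = 1350, f2_off = 1300, dur = 0.12),
  aa  = c(f1_on = 900, f1_off = 880, f2_on = 1400, f2_off = 1350, dur = 0.28)
)

#' Generate a synthetic talker cohort
#'
#' Draws a cohort of synthetic talkers over a minimal-pair word roster. Each
#' talker gets a base f0, a multiplicative vocal-tract (formant) idiosyncrasy,
#' a speech-rate idiosyncrasy, and a per-pair contrast-separation parameter
#' `delta >= 0`: the scale on which the talker separates the two words of the
#' pair around their phonetic midpoint (`delta = 1` reproduces the canonical
#' separation; `delta = 0` collapses the pair). `delta` is drawn log-normal so
#' that ranked contrastiveness groups are all populated.
#'
#' @param n_talkers number of talkers (>= 5).
#' @param n_pairs number of minimal pairs (>= 1). Up to 13 pairs come from
#'   the built-in stimulus roster; beyond that, pairs are recycled with fresh
#'   identifiers.
#' @param seed RNG seed; cohorts are reproducible given the seed.
#' @param delta_meanlog,delta_sdlog log-normal parameters of the per
#'   talker-by-pair contrast separation.
#' @param f0_mean,f0_sd talker base f0 distribution (Hz; adult female).
#' @return an `ownvoice_cohort`: list with `talkers` (talker_id, f0_base,
#'   formant_shift, speech_rate), `delta` (talker_id, pair_id, delta),
#'   `roster` (pair/word table with synthesis targets) and `words`.
#' @export
make_cohort <- function(n_talkers, n_pairs, seed = 1,
                        delta_meanlog = 0, delta_sdlog = 0.4,
                        f0_mean = 210, f0_sd = 20) {
  n_talkers <- stopifnot_scalar_count(n_talkers, "n_talkers", min = 5L)
  n_pairs <- stopifnot_scalar_count(n_pairs, "n_pairs", min = 1L)
  base <- stimulus_roster()
  if (n_pairs <= nrow(base)) {
    pairs <- base[seq_len(n_pairs), ]
  } else {
    extra_n <- n_pairs - nrow(base)
    idx <- rep_len(seq_len(nrow(base)), extra_n)
    extra <- base[idx, ]
    extra$pair_id <- sprintf("x%02d", seq_len(extra_n))
    extra$word_a <- paste0(extra$word_a, "_", extra$pair_id)
    extra$word_b <- paste0(extra$word_b, "_", extra$pair_id)
    pairs <- rbind(base, extra)
  }
  words <- roster_words(pairs)
  nuc <- jyutping_nucleus(sub("_x[0-9]+$", "", words$word_id))
  unknown <- setdiff(unique(nuc), names(NUCLEUS_TARGETS))
  if (length(unknown)) stop("no synthesis targets for nucleus: ",
                            paste(unknown, collapse = ", "))
  tg <- do.call(rbind, NUCLEUS_TARGETS[nuc])
  words <- cbind(words, as.data.frame(tg))
  with_seed(seed, {
    talkers <- data.frame(
      talker_id = sprintf("T%02d", seq_len(n_talkers)),
      f0_base = pmax(120, rnorm(n_talkers, f0_mean, f0_sd)),
      formant_shift = rlnorm(n_talkers, 0, 0.05),
      speech_rate = rlnorm(n_talkers, 0, 0.08)
    )
    delta <- expand.grid(talker_id = talkers$talker_id,
                         pair_id = pairs$pair_id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    delta <- delta[order(delta$talker_id, delta$pair_id), ]
    rownames(delta) <- NULL
    delta$delta <- rlnorm(nrow(delta), delta_meanlog, delta_sdlog)
    structure(list(talkers = talkers, delta = delta, roster = pairs,
                   words = words,
                   config = list(seed = seed, delta_meanlog = delta_meanlog,
                                 delta_sdlog = delta_sdlog)),
              class = "ownvoice_cohort")
  })
}

#' @export
print.ownvoice_cohort <- function(x, ...) {
  cat(sprintf("ownvoice cohort: %d talkers x %d minimal pairs (%d words)\n",
              nrow(x$talkers), nrow(x$roster), length(unique(x$words$word_id))))
  invisible(x)
}

# Realized word targets for one talker. Pairs are processed in roster order;
# a fresh pair is realized around its canonical midpoint at delta-scaled
# separation, while a pair sharing a word with an earlier pair keeps the
# shared word's realized target and extends the other member from it by
# delta times the canonical difference — so every pair's expected separation
# is proportional to its own delta. Talker idiosyncrasies (formant shift,
# speech rate) are applied afterwards.
talker_word_targets <- function(cohort, talker_id) {
  tk <- cohort$talkers[cohort$talkers$talker_id == talker_id, ]
  if (!nrow(tk)) stop("unknown talker: ", talker_id)
  par_names <- c("f1_on", "f1_off", "f2_on", "f2_off", "dur")
  dls <- cohort$delta[cohort$delta$talker_id == talker_id, ]
  realized <- list()
  for (i in seq_len(nrow(cohort$roster))) {
    p <- cohort$roster$pair_id[i]
    rows <- cohort$words[cohort$words$pair_id == p, ]
    ida <- rows$word_id[rows$slot == "a"][1]
    idb <- rows$word_id[rows$slot == "b"][1]
    ta <- unlist(rows[rows$slot == "a", par_names][1, ])
    tb <- unlist(rows[rows$slot == "b", par_names][1, ])
    dl <- dls$delta[dls$pair_id == p]
    a_done <- !is.null(realized[[ida]])
    b_done <- !is.null(realized[[idb]])
    if (!a_done && !b_done) {
      mid <- (ta + tb) / 2
      realized[[ida]] <- mid + (ta - mid) * dl
      realized[[idb]] <- mid + (tb - mid) * dl
    } else if (a_done && !b_done) {
      realized[[idb]] <- realized[[ida]] + (tb - ta) * dl
    } else if (b_done && !a_done) {
      realized[[ida]] <- realized[[idb]] + (ta - tb) * dl
    }
  }
  lapply(realized, function(tgt) {
    tgt[1:4] <- pmax(150, tgt[1:4] * tk$formant_shift)
    tgt["dur"] <- max(0.05, tgt["dur"] * tk$speech_rate)
    tgt
  })
}

word_targets_for_talker <- function(cohort, talker_id, word_id) {
  w <- cohort$words[cohort$words$word_id == word_id, ]
  if (!nrow(w)) stop("unknown word: ", word_id)
  tk <- cohort$talkers[cohort$talkers$talker_id == talker_id, ]
  if (!nrow(tk)) stop("unknown talker: ", talker_id)
  all_tgt <- talker_word_targets(cohort, talker_id)
  list(target = all_tgt[[word_id]], pair_id = w$pair_id[1L],
       f0_base = tk$f0_base)
}

#' Synthesize one vowel production
#'
#' Produces one repetition of one word by one talker: cosine-eased F1/F2
#' trajectories between the delta-scaled onset/offset targets, a declining
#' level-tone f0 contour, and (optionally) source-filter audio — a glottal
#' pulse train through cascaded second-order resonators at the trajectory's
#' formant values plus a fixed F3 — so formant measurement can recover the
#' generating trajectory.
#'
#' @param cohort an `ownvoice_cohort`.
#' @param talker_id,word_id identify the production; `repetition` is 1 or 2.
#' @param jitter multiplicative repetition noise (log-normal SD) applied to
#'   each formant trajectory and to duration; `0` gives identical repetitions.
#' @param with_audio synthesize a 44.1 kHz mono waveform.
#' @param n_samples trajectory length (uniform time steps).
#' @param fs audio sample rate (Hz).
#' @return a `vowel_token`: list with `talker_id`, `word_id`, `pair_id`,
#'   `repetition`, `times`, `f1_track`, `f2_track`, `f0_track`, `duration`,
#'   `audio` (or NULL), `fs`.
#' @export
synthesize_token <- function(cohort, talker_id, word_id, repetition = 1L,
                             jitter = 0.02, with_audio = FALSE,
                             n_samples = 20L, fs = 44100) {
  stopifnot(inherits(cohort, "ownvoice_cohort"), jitter >= 0)
  wt <- word_targets_for_talker(cohort, talker_id, word_id)
  tgt <- wt$target
  jf1 <- if (jitter > 0) rlnorm(1, 0, jitter) else 1
  jf2 <- if (jitter > 0) rlnorm(1, 0, jitter) else 1
  jdur <- if (jitter > 0) rlnorm(1, 0, jitter) else 1
  s <- seq(0, 1, length.out = n_samples)
  ease <- (1 - cos(pi * s)) / 2
  f1 <- pmax(150, (tgt["f1_on"] + (tgt["f1_off"] - tgt["f1_on"]) * ease) * jf1)
  f2 <- (tgt["f2_on"] + (tgt["f2_off"] - tgt["f2_on"]) * ease) * jf2
  f2 <- pmax(f2, f1 + 150)
  dur <- unname(tgt["dur"] * jdur)
  f0 <- wt$f0_base * seq(1.04, 0.96, length.out = n_samples) *
    (if (jitter > 0) rlnorm(1, 0, jitter / 2) else 1)
  token <- structure(list(
    talker_id = talker_id, word_id = word_id, pair_id = wt$pair_id,
    repetition = as.integer(repetition), times = s * dur,
    f1_track = unname(f1), f2_track = unname(f2), f0_track = unname(f0),
    duration = dur, audio = NULL, fs = fs), class = "vowel_token")
  if (with_audio) token$audio <- synthesize_vowel_audio(
    f1, f2, f0, dur, fs = fs)
  token
}

#' Source-filter vowel synthesis
#'
#' Glottal pulse train at a time-varying f0 passed through cascaded two-pole
#' resonators at time-varying F1/F2 plus a fixed third formant.
#'
#' @param f1,f2 formant trajectories (Hz, uniform time steps over the vowel).
#' @param f0 f0 trajectory (Hz).
#' @param duration seconds.
#' @param fs sample rate.
#' @param f3 fixed third-formant frequency (Hz).
#' @param bandwidths formant bandwidths (Hz).
#' @return numeric waveform, peak-normalized to 0.3.
#' @export
synthesize_vowel_audio <- function(f1, f2, f0, duration, fs = 44100,
                                   f3 = 2800, bandwidths = c(80, 90, 140)) {
  n <- max(16L, round(duration * fs))
  tt <- seq(0, 1, length.out = n)
  grid <- seq(0, 1, length.out = length(f1))
  f1s <- approx(grid, f1, tt)$y
  f2s <- approx(grid, f2, tt)$y
  f0s <- approx(seq(0, 1, length.out = length(f0)), f0, tt)$y
  # glottal source: impulse train by accumulated phase, mild spectral tilt
  phase <- cumsum(f0s) / fs
  pulses <- c(0, diff(floor(phase))) > 0
  src <- as.numeric(pulses)
  src <- stats::filter(src, filter = 0.9, method = "recursive")  # -6 dB/oct tilt
  src <- as.numeric(src)
  out <- .resonate_cascade(src, cbind(f1s, f2s, rep(f3, n)), bandwidths, fs)
  ramp <- pmin(1, seq_len(n) / (0.01 * fs), rev(seq_len(n)) / (0.01 * fs))
  out <- out * ramp
  out / max(abs(out)) * 0.3
}

#' Synthesize a full production set
#'
#' All talkers x all words x `reps` repetitions, reproducibly under `seed`.
#'
#' @param cohort an `ownvoice_cohort`.
#' @param reps repetitions per word (the production task uses 2).
#' @param jitter,with_audio,fs passed to [synthesize_token()].
#' @param seed RNG seed.
#' @return list of `vowel_token`s.
#' @export
synthesize_production_set <- function(cohort, reps = 2L, jitter = 0.02,
                                      with_audio = FALSE, fs = 44100,
                                      seed = 1) {
  grid <- expand.grid(rep = seq_len(reps),
                      word = unique(cohort$words$word_id),
                      talker = cohort$talkers$talker_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      synthesize_token(cohort, grid$talker[i], grid$word[i], grid$rep[i],
                       jitter = jitter, with_audio = with_audio, fs = fs)
    })
  })
}
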