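fs <- 44100

test_that("RMS normalization hits the Praat-convention target exactly", {
  with_seed_local(1, x <- rnorm(4000, 0, 0.2))
  y <- rms_normalize(x, 65)
  expect_lt(abs(sqrt(mean(y^2)) - 0.035566), 1e-6)
  expect_equal(rms_normalize(y, 65), y, tolerance = 1e-12)   # idempotent
  expect_error(rms_normalize(rep(0, 100)), "silent")
  y40 <- rms_normalize(x, 40)
  expect_lt(abs(sqrt(mean(y40^2)) - 2e-5 * 10^2), 1e-9)
})

test_that("SNR mixing applies the closed-form noise gain", {
  with_seed_local(2, {
    s <- rnorm(8000, 0, 0.1)
    n <- rnorm(10000, 0, 0.1)
  })
  s_eq <- s
  n_eq <- n * sqrt(mean(s^2)) / sqrt(mean(n[seq_along(s)]^2))  # equal RMS
  m0 <- mix_at_snr(s_eq, n_eq, 0)
  expect_equal(attr(m0, "noise_gain"), 1, tolerance = 1e-6)
  m5 <- mix_at_snr(s_eq, n_eq, 5)
  expect_equal(attr(m5, "noise_gain"), 10^(-5 / 20), tolerance = 1e-6)
  # measured SNR of the mixed components equals the request to 0.01 dB
  g <- attr(m5, "noise_gain")
  snr_meas <- 20 * log10(sqrt(mean(s_eq^2)) /
                           sqrt(mean((g * n_eq[seq_along(s_eq)])^2)))
  expect_equal(snr_meas, 5, tolerance = 0.01)
  expect_error(mix_at_snr(s_eq, n_eq[1:10], 5), "at least as long")
  expect_error(mix_at_snr(rep(0, 100), n_eq, 5), "non-silent")
})

test_that("speech-shaped noise reproduces the corpus LTAS", {
  # white-noise corpus -> flat output spectrum
  wn <- with_seed_local(3, rnorm(2 * fs))
  nz <- speech_shaped_noise(list(wn), 2, fs, seed = 4)
  l <- ltas(nz, fs, smooth_bins = 9)
  band <- l$freq >= 100 & l$freq <= 8000
  dev <- l$level_db[band] - mean(l$level_db[band])
  expect_lt(max(abs(dev)), 3)
  # sine-dominated corpus -> spectral peak at the sine frequency
  tt <- seq_len(2 * fs) / fs
  sine <- sin(2 * pi * 1000 * tt) + 0.01 * with_seed_local(5, rnorm(2 * fs))
  nz2 <- speech_shaped_noise(list(sine), 2, fs, seed = 6)
  l2 <- ltas(nz2, fs)
  expect_lt(abs(l2$freq[which.max(l2$level_db)] - 1000), 50)
  # multi-talker vowel corpus: self-consistency at envelope resolution
  corpus <- with_seed_local(7, lapply(1:8, function(i) {
    synthesize_vowel_audio(rep(runif(1, 400, 900), 20),
                           rep(runif(1, 900, 2200), 20),
                           runif(1, 180, 260) * seq(1.08, 0.92, length.out = 20),
                           0.35, fs)
  }))
  nz3 <- speech_shaped_noise(corpus, 3, fs, seed = 8)
  lc <- ltas(unlist(corpus), fs, smooth_bins = 9)
  ln <- ltas(nz3, fs, smooth_bins = 9)
  band <- lc$freq >= 100 & lc$freq <= 8000
  d <- (ln$level_db - lc$level_db)[band]
  d <- d - mean(d)
  expect_lt(max(abs(d)), 3)
  # deterministic under seed
  expect_identical(as.numeric(nz3), as.numeric(speech_shaped_noise(corpus, 3, fs, seed = 8)))
  expect_error(speech_shaped_noise(list(), 1, fs), "empty corpus")
  expect_error(speech_shaped_noise(list(rnorm(100)), 1, fs), "at least 1 s")
})

test_that("identity disguise on the parametric path returns the input", {
  co <- tiny_cohort()
  tok <- synthesize_token(co, co$talkers$talker_id[1], "go1", 1,
                          jitter = 0, with_audio = TRUE)
  same <- disguise(tok, disguise_spec(1, 1))
  expect_equal(same$f0_track, tok$f0_track)
  expect_equal(same$f1_track, tok$f1_track)
  expect_equal(same$audio, tok$audio, tolerance = 1e-12)
  expect_error(disguise_spec(0, 0.8), "factors")
  expect_error(disguise_spec(0.6, 1.2), "factors")
})

test_that("disguise scales formants and f0 by the requested factors", {
  f0c <- 210 * seq(1.04, 0.96, length.out = 20)
  aud <- synthesize_vowel_audio(rep(500, 20), rep(1500, 20), f0c, 0.3, fs)
  sp <- disguise_spec(0.62, 0.81)
  out <- disguise(aud, sp, fs = fs)
  # duration within 2%
  expect_lt(abs(length(out) / length(aud) - 1), 0.02)
  trk <- measure_formants(as.numeric(out), fs, ceiling = 5500)
  expect_lt(abs(mean(trk$f1) / 405 - 1), 0.05)
  expect_lt(abs(mean(trk$f2) / 1215 - 1), 0.05)
  # f0: 200-Hz token through the default factors lands near 124 Hz
  aud200 <- synthesize_vowel_audio(rep(500, 20), rep(1500, 20), rep(200, 20),
                                   0.3, fs)
  out200 <- disguise(aud200, sp, fs = fs)
  expect_lt(abs(estimate_f0(as.numeric(out200), fs) / (200 * 0.62) - 1), 0.05)
})

test_that("parametric and DSP disguise paths agree on measured formants", {
  co <- tiny_cohort()
  tok <- synthesize_token(co, co$talkers$talker_id[4], "so1", 1,
                          jitter = 0, with_audio = TRUE)
  sp <- disguise_spec(0.62, 0.81)
  par_tok <- disguise(tok, sp)
  dsp_aud <- disguise(tok$audio, sp, fs = tok$fs)
  t_par <- measure_formants(par_tok$audio, tok$fs, ceiling = 5000)
  t_dsp <- measure_formants(as.numeric(dsp_aud), tok$fs, ceiling = 5000)
  expect_lt(abs(mean(t_par$f1) / mean(t_dsp$f1) - 1), 0.07)
  expect_lt(abs(mean(t_par$f2) / mean(t_dsp$f2) - 1), 0.07)
})

test_that("disguise preserves the contrastiveness ordering", {
  # formant scaling hits both pair members alike, so z-scored distances on
  # disguised tokens should track pre-disguise distances despite the
  # nonlinear Hz -> Bark warp
  co <- make_cohort(12, 3, seed = 31)
  toks <- synthesize_production_set(co, reps = 2, jitter = 0.02, seed = 32)
  sp <- disguise_spec(0.62, 0.81)
  pre <- feature_table(toks)
  post <- feature_table(lapply(toks, disguise, spec = sp))
  sc_pre <- contrast_scores(pre, co$roster)
  sc_post <- contrast_scores(post, co$roster)
  m <- merge(sc_pre, sc_post, by = c("pair_id", "talker_id"))
  expect_gte(cor(m$distance.x, m$distance.y, method = "spearman"), 0.8)
})

test_that("the full stimulus chain yields a correctly leveled, mixed token", {
  co <- tiny_cohort()
  tok <- synthesize_token(co, co$talkers$talker_id[2], "sou1", 1,
                          jitter = 0, with_audio = TRUE)
  dis <- disguise(tok$audio, disguise_spec(0.62, 0.81), fs = tok$fs)
  lev <- rms_normalize(as.numeric(dis), 65)
  corpus <- with_seed_local(33, lapply(1:4, function(i)
    synthesize_vowel_audio(rep(runif(1, 400, 800), 20),
                           rep(runif(1, 900, 1800), 20),
                           rep(runif(1, 180, 240), 20), 0.4, fs)))
  noise <- speech_shaped_noise(corpus, length(lev) / fs + 0.4, fs, seed = 34)
  mixed <- mix_at_snr(lev, as.numeric(noise), 5)
  g <- attr(mixed, "noise_gain")
  snr <- 20 * log10(sqrt(mean(lev^2)) /
                      sqrt(mean((g * as.numeric(noise)[seq_along(lev)])^2)))
  expect_equal(snr, 5, tolerance = 0.01)
  expect_equal(length(mixed), length(lev))
  expect_lt(abs(length(lev) / length(tok$audio) - 1), 0.02)
})
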