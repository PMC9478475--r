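# shared fixtures and independent oracles

# brute-force DCT-II oracle: direct O(N^2) evaluation of the cosine sums,
# scaled so c0 is the mean (independent of the package's FFT route)
dct_oracle <- function(x, n_coef = 3) {
  N <- length(x)
  vapply(seq_len(n_coef) - 1, function(k) {
    s <- sum(x * cos(pi * k * (2 * seq_len(N) - 1) / (2 * N)))
    if (k == 0) s / N else 2 * s / N
  }, numeric(1))
}

# series oracle for Polya-Gamma moments: PG(1,z) is an infinite weighted sum
# of exponentials with known coefficients
pg_moment_oracle <- function(z, nterms = 2e5) {
  k <- seq_len(nterms)
  d <- (k - 0.5)^2 + z^2 / (4 * pi^2)
  c(mean = sum(1 / d) / (2 * pi^2), var = sum(1 / d^2) / (2 * pi^2)^2)
}

# small standing cohort for feature / contrast tests
tiny_cohort <- function(n_talkers = 8, n_pairs = 6, seed = 101) {
  make_cohort(n_talkers, n_pairs, seed = seed)
}

# hand-built trial design for inference tests (no acoustics involved)
toy_design <- function(S = 10, npt = 80, seed = 1, n_groups = 5) {
  with_seed_local(seed, {
    data.frame(
      participant = rep(sprintf("P%02d", seq_len(S)), each = npt),
      own_voice = rbinom(S * npt, 1, 1 / 6) == 1,
      trial_index = as.vector(replicate(S, sample(npt))),
      group = factor(sample(LETTERS[seq_len(n_groups)], S * npt, TRUE),
                     levels = LETTERS[seq_len(n_groups)])
    )
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# simulate correctness for a design from explicit coefficients (bypasses
# response_gen_params so tests control every term)
simulate_from_beta <- function(design, beta, re_sd = c(0, 0, 0), seed = 1) {
  d <- build_design(design)
  S <- length(d$participants)
  with_seed_local(seed, {
    U <- cbind(rnorm(S, 0, re_sd[1]), rnorm(S, 0, re_sd[2]),
               rnorm(S, 0, re_sd[3]))
    eta <- as.vector(d$X %*% beta) +
      rowSums(U[d$participant_index, , drop = FALSE] * d$re_covariates)
    design$correct <- rbinom(length(eta), 1, plogis(eta))
    design
  })
}
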