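#' Parameters of the 2AFC response generator
#'
#' Generating values for simulated listeners: fixed effects on the log-odds
#' scale laid out exactly as the accuracy model's design matrix (intercept;
#' treatment-coded Voice Match; centered/scaled Trial; forward-difference
#' Group contrasts; Voice Match x Group, Trial x Group, Voice Match x Trial
#' interactions), correlated by-participant random effects, and a log-normal
#' reaction-time generator with a small contamination rate outside the
#' 200-5000 ms window. Defaults are the fitted posterior point estimates of
#' the word-recognition accuracy model and field-plausible RE/RT settings.
#'
#' @param b_intercept,b_own,b_trial,b_own_trial scalar log-odds effects.
#' @param b_group,b_own_group,b_trial_group adjacent-level (forward
#'   difference) effects, length `n_groups - 1`.
#' @param re_sd SDs of the by-participant random intercept, Voice Match slope
#'   and Trial slope.
#' @param re_corr 3x3 random-effect correlation matrix.
#' @param rt_meanlog,rt_sdlog log-normal RT parameters (ms).
#' @param rt_contamination probability of an out-of-range RT.
#' @return list of generator parameters (class `response_gen_params`).
#' @export
response_gen_params <- function(b_intercept = 1.66, b_own = 0.23,
                                b_trial = 0.07,
                                b_group = c(-0.21, 0.27, 0.21, 0.26),
                                b_own_group = c(0.31, -0.41, 0.31, -0.04),
                                b_trial_group = c(0.08, -0.04, -0.03, -0.04),
                                b_own_trial = 0.03,
                                re_sd = c(0.5, 0.3, 0.1),
                                re_corr = default_re_corr(),
                                rt_meanlog = log(900), rt_sdlog = 0.35,
                                rt_contamination = 0.02) {
  stopifnot(length(b_group) == length(b_own_group),
            length(b_group) == length(b_trial_group),
            all(re_sd >= 0), length(re_sd) == 3L,
            rt_contamination >= 0, rt_contamination < 1)
  if (!isTRUE(all.equal(re_corr, t(re_corr))) ||
      !isTRUE(all.equal(unname(diag(re_corr)), rep(1, 3))) ||
      any(eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("re_corr must be a symmetric positive-definite correlation matrix")
  }
  structure(list(b_intercept = b_intercept, b_own = b_own, b_trial = b_trial,
                 b_group = b_group, b_own_group = b_own_group,
                 b_trial_group = b_trial_group, b_own_trial = b_own_trial,
                 re_sd = re_sd, re_corr = re_corr,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_contamination = rt_contamination),
            class = "response_gen_params")
}

#' @rdname response_gen_params
#' @export
default_re_corr <- function() {
  m <- matrix(0.2, 3, 3)
  diag(m) <- 1
  m
}

# fixed-effect vector in build_design column order
gen_params_beta <- function(params) {
  c(params$b_intercept, params$b_own, params$b_trial,
    params$b_group, params$b_own_group, params$b_trial_group,
    params$b_own_trial)
}

#' Simulate 2AFC responses for an experiment design
#'
#' Draws per-participant random effects from the generator's correlated
#' multivariate normal, assembles each trial's log-odds through the same
#' design-matrix code the accuracy model fits ([build_design()]), and draws
#' correctness as Bernoulli(logistic(eta)). Reaction times are log-normal,
#' truncated into the valid 200-5000 ms window, except for a configured
#' contamination fraction drawn outside it (half too fast, half too slow).
#'
#' @param design ordered trial table (e.g. from [build_experiment()]) with
#'   columns `participant`, `voice_id`, `own_voice`, `pair_id`, `word_id`,
#'   `group`, `trial_index`, `block`.
#' @param params a [response_gen_params()] object.
#' @param seed RNG seed.
#' @param group_levels explicit group level order (defaults to sorted unique).
#' @return `design` plus `correct` (0/1), `chosen_word_id` and `rt_ms`.
#' @export
simulate_trials <- function(design, params = response_gen_params(), seed = 1,
                            group_levels = NULL) {
  stopifnot(inherits(params, "response_gen_params"))
  d <- build_design(design, group_levels = group_levels)
  k <- length(d$group_levels)
  if (length(params$b_group) != k - 1L) {
    stop(sprintf("params specify %d adjacent-group effects but design has %d groups",
                 length(params$b_group), k))
  }
  beta <- gen_params_beta(params)
  S <- length(d$participants)
  with_seed(seed, {
    sig <- diag(params$re_sd) %*% params$re_corr %*% diag(params$re_sd)
    U <- if (all(params$re_sd == 0)) matrix(0, S, 3) else rmvnorm_chol(S, sig)
    eta <- as.vector(d$X %*% beta) +
      rowSums(U[d$participant_index, , drop = FALSE] * d$re_covariates)
    correct <- rbinom(length(eta), 1L, plogis(eta))
    n <- length(eta)
    rt <- rlnorm(n, params$rt_meanlog, params$rt_sdlog)
    bad <- rt < 200 | rt > 5000
    while (any(bad)) {  # clean RTs live inside the window
      rt[bad] <- rlnorm(sum(bad), params$rt_meanlog, params$rt_sdlog)
      bad <- rt < 200 | rt > 5000
    }
    contam <- runif(n) < params$rt_contamination
    if (any(contam)) {
      fast <- contam & runif(n) < 0.5
      slow <- contam & !fast
      rt[fast] <- runif(sum(fast), 50, 199)
      rt[slow] <- runif(sum(slow), 5001, 9000)
    }
    out <- design
    out$correct <- correct
    out$rt_ms <- rt
    out$chosen_word_id <- other_pair_word(design)
    out$chosen_word_id[correct == 1L] <- design$word_id[correct == 1L]
    out
  })
}

# the pair-mate of each trial's intended word, inferred from the design
other_pair_word <- function(design) {
  key <- paste(design$pair_id, design$word_id)
  pair_words <- tapply(design$word_id, design$pair_id,
                       function(w) sort(unique(w)), simplify = FALSE)
  vapply(seq_len(nrow(design)), function(i) {
    w <- pair_words[[design$pair_id[i]]]
    if (length(w) != 2L) return(design$word_id[i])
    if (w[1] == design$word_id[i]) w[2] else w[1]
  }, character(1))
}
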