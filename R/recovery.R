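#' Full-pipeline simulation-recovery study
#'
#' Runs the whole artifact end to end on synthetic data: generate a talker
#' cohort, synthesize two repetitions of every word, featurize, score
#' contrastiveness and assign groups per pair, build every participant's
#' personalized 2AFC experiment, simulate responses from the generating
#' fixed effects, apply the reaction-time filter, and fit the Bayesian
#' multilevel accuracy model. The returned summary lets each generating
#' coefficient be compared with its recovered posterior.
#'
#' @param seed master seed; all stages derive their seeds from it.
#' @param n_talkers,n_pairs cohort size (defaults mirror the study: 33
#'   talkers, 13 minimal pairs).
#' @param reps presentation repetitions per token.
#' @param params generating [response_gen_params()].
#' @param chains,iter,warmup sampler configuration.
#' @param jitter production repetition noise.
#' @return list with `fit` (an `ownvoice_fit`), `summary` (posterior
#'   summaries of the fixed effects), `generating` (named generating values
#'   in design-matrix order), `n_trials`, `removed_fraction`, `assignments`.
#' @export
recovery_study <- function(seed = 1, n_talkers = 33, n_pairs = 13, reps = 4,
                           params = response_gen_params(),
                           chains = 4, iter = 4000, warmup = 1000,
                           jitter = 0.02) {
  co <- make_cohort(n_talkers, n_pairs, seed = seed)
  toks <- synthesize_production_set(co, reps = 2, jitter = jitter,
                                    seed = seed + 1L)
  ft <- feature_table(toks)
  sc <- contrast_scores(ft, co$roster)
  asg <- assign_groups_all(sc)
  des <- build_experiment(asg, co$roster, reps = reps, seed = seed + 2L)
  tr <- simulate_trials(des, params, seed = seed + 3L)
  flt <- filter_rt(tr)
  fit <- fit_accuracy_model(flt$trials, chains = chains, iter = iter,
                            warmup = warmup, seed = seed + 4L,
                            group_levels = LETTERS[1:5])
  gen <- gen_params_beta(params)
  names(gen) <- colnames(build_design(flt$trials,
                                      group_levels = LETTERS[1:5])$X)
  list(fit = fit,
       summary = summarize_posterior(fit, parameters = names(gen)),
       generating = gen,
       n_trials = nrow(flt$trials),
       removed_fraction = flt$removed_fraction,
       assignments = asg)
}
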