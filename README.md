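# ownvoice

Tools for studying the **own-voice benefit** in spoken-word recognition:
listeners identifying words in noise tend to be more accurate when the words
were produced in their own (even disguised) voice. The package implements the
complete computational pipeline of such a study around Cantonese vowel
minimal pairs, for phoneticians and psycholinguists who want to score
production contrastiveness, build personalized perception experiments, and
fit the corresponding Bayesian accuracy model — or simulate the whole study
when no recordings are at hand.

## What it computes

**Contrastiveness.** For each talker and minimal pair (e.g. *sam1* "heart" ~
*saam1* "shirt"), each word is summarized by seven dimensions: the first
three DCT coefficients (mean, slope, curvature) of the Bark-scaled F1 and F2
trajectories, plus vowel duration. Within a pair, all word-vectors are
z-scored across talkers and the talker's contrastiveness is the Euclidean
distance between their two words,

d(a, b) = sqrt( sum_{i=1..7} (z_i(a) - z_i(b))^2 ),

with larger distances meaning more distinct productions. Talkers are ranked
per pair into five groups, A (most contrastive) through E, of five to seven
voices.

**Stimulus preparation.** Vocal disguise by multiplicative f0/formant
lowering (defaults 0.62 and 0.81; parametric resynthesis or a
resampling + LP-PSOLA waveform path), RMS normalization to 65 dB SPL (Praat
convention), speech-shaped noise generated from a corpus spectrum, and mixing
at +5 dB SNR.

**Experiment construction.** Each participant hears their own productions
and those of their group mates, for every pair they produced, two words x
group voices x four repetitions, fully randomized into four blocks; responses
under 200 ms or over 5000 ms are discarded.

**Inference.** Trial-level correctness is modeled as Bernoulli-logit with
Voice Match (treatment coded), Trial (centered/scaled), Group
(forward-difference coded), their stated interactions, and correlated
by-participant random intercepts and slopes; priors are Normal(0, 5) on the
intercept, Normal(0, 2.5) on other fixed effects, LKJ(2) on the
random-effect correlations. Sampling is by an exact Polya-Gamma Gibbs
sampler with an interweaving move for the random-effect scales; summaries
report posterior medians, equal-tailed 95% credible intervals and the
probability of direction. Split R-hat and bulk ESS diagnostics are computed
for every monitored parameter.

**Synthetic data.** A generator draws talker cohorts with a per-talker,
per-pair separation parameter delta (expected contrast distance is
proportional to delta), synthesizes formant trajectories and optional
source-filter audio, and simulates 2AFC responses from the same design
matrix the model fits — so the full pipeline runs end to end with no
downloads.

## Worked example

```r
library(ownvoice)

co   <- make_cohort(n_talkers = 33, n_pairs = 13, seed = 7)
toks <- synthesize_production_set(co, reps = 2, jitter = 0.02, seed = 8)
ft   <- feature_table(toks)                 # one 7-D vector per talker x word
sc   <- contrast_scores(ft, co$roster)      # distances + ranks per pair
asg  <- assign_groups_all(sc)               # groups A-E per pair

head(subset(asg, pair_id == "p11"), 8)
#>     pair_id talker_id group distance rank
#> 331     p11       T08     A 8.314002    1
#> 332     p11       T15     A 7.147782    2
#> 333     p11       T14     A 6.914405    3
#> 334     p11       T32     A 6.424916    4
#> 335     p11       T30     A 6.280500    5
#> 336     p11       T21     A 5.569245    6
#> 337     p11       T26     A 5.006456    7
#> 338     p11       T25     B 4.980726    8
table(subset(asg, pair_id == "p11")$group)
#> A B C D E
#> 7 7 7 6 6

des <- build_experiment(asg, co$roster, seed = 9)   # personalized 2AFC rosters
tr  <- simulate_trials(des, response_gen_params(), seed = 10)
flt <- filter_rt(tr)
#> 22776 trials simulated; 1.9% removed by the RT filter
#> accuracy: own voice 0.822, other voices 0.808

fit <- fit_accuracy_model(flt$trials, chains = 2, iter = 2600,
                          warmup = 600, seed = 11)
summarize_posterior(fit, parameters = c("(Intercept)", "own", "trial", "BvC"))
#>     parameter median cri_low cri_high    pd
#> 1 (Intercept) 1.4801  1.3203    1.647 1.000
#> 2         own 0.1656  0.0263    0.319 0.990
#> 3       trial 0.0679  0.0111    0.129 0.989
#> 4         BvC 0.2930  0.1709    0.413 1.000
```

The distances order talkers within the pair (group sizes 7/7/7/6/6 at 33
talkers); the simulated study then shows the generated own-voice advantage:
the `own` coefficient's posterior (median 0.17 log-odds, CrI excluding 0,
pd 0.99) recovers the generating effect of 0.23 within its credible
interval, and `BvC` the generated adjacent-group difference. A production
analysis would use the full sampler configuration
(`chains = 4, iter = 4000, warmup = 1000`).

`tokens_from_annotations()` is the entry point for real recordings: a CSV of
(talker, word, pair, start/end time, WAV file) plus a directory of mono
PCM-16 WAV files yields the same `vowel_token` objects the synthetic path
produces.

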