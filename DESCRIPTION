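Package: ownvoice
Title: Minimal-Pair Contrastiveness and Own-Voice Word Recognition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the own-voice benefit in word recognition with
    vowel minimal pairs. Scores how contrastively a talker produces each
    minimal pair (Bark-scaled formant-trajectory DCT coefficients plus
    duration, z-scored 7-D Euclidean distance) and ranks talkers into
    contrastiveness groups; prepares perception stimuli (pitch/formant-scaled
    vocal disguise, RMS normalization, speech-shaped noise mixing at a target
    SNR); builds personalized two-alternative forced-choice experiments; and
    fits a Bayesian multilevel logistic regression to trial-level accuracy
    with a Polya-Gamma Gibbs sampler. Includes a synthetic-talker and
    simulated-listener generator so the full pipeline runs end to end without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
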