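#' Cantonese minimal-pair stimulus roster
#'
#' The 13 vowel minimal pairs (level tone T1) used in the perception task,
#' as Jyutping romanizations with English glosses. One word ("chicken",
#' `gai1`) takes part in two pairs, so the roster holds 25 unique words.
#'
#' @param path roster file (tab-separated, one row per pair with columns
#'   `pair_id`, `word_a`, `gloss_a`, `word_b`, `gloss_b`). Defaults to the
#'   roster shipped with the package.
#' @return data frame, one row per minimal pair.
#' @examples
#' r <- stimulus_roster()
#' nrow(r)                                   # 13 pairs
#' length(unique(c(r$word_a, r$word_b)))     # 25 unique words
#' @export
stimulus_roster <- function(path = system.file("extdata", "perception_stimuli.tsv",
                                               package = "ownvoice")) {
  r <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "word_a", "gloss_a", "word_b", "gloss_b")
  miss <- setdiff(req, names(r))
  if (length(miss)) stop("roster is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(r$pair_id)) stop("duplicate pair_id in roster")
  r
}

#' Long-format word list of a roster
#'
#' @param roster as returned by [stimulus_roster()].
#' @return data frame with one row per (pair, word): `pair_id`, `word_id`,
#'   `gloss`, `slot` ("a" or "b").
#' @export
roster_words <- function(roster = stimulus_roster()) {
  rbind(
    data.frame(pair_id = roster$pair_id, word_id = roster$word_a,
               gloss = roster$gloss_a, slot = "a"),
    data.frame(pair_id = roster$pair_id, word_id = roster$word_b,
               gloss = roster$gloss_b, slot = "b")
  )[order(rep(seq_len(nrow(roster)), 2L)), ]
}

# Jyutping rime -> vowel nucleus used by the synthesizer. Strips the tone
# digit and the onset; a final m/n/ng/p/t/k is a coda, the rest (incl. the
# i/u offglides) is the nucleus.
jyutping_nucleus <- function(word) {
  vapply(word, function(w) {
    w <- gsub("[0-9]+$", "", w)
    w <- sub("^(gw|kw|ng|[bpmfdtnlgkhwzcsj])", "", w)
    sub("(ng|[mnptk])$", "", w)
  }, character(1), USE.NAMES = FALSE)
}
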