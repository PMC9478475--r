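#' Build a participant's personalized 2AFC roster
#'
#' For every minimal pair where the participant has productions of both
#' words, the roster crosses the pair's two words with the voices of the
#' participant's contrastiveness group for that pair (their own voice
#' included) and `reps` presentation repetitions. A voice missing either word
#' of a pair contributes neither word of that pair; a participant missing
#' either of their own words skips the pair entirely.
#'
#' @param participant talker/participant identifier.
#' @param assignments stacked group assignments (`pair_id`, `talker_id`,
#'   `group`) from [assign_groups()].
#' @param roster pair/word table (defaults to [stimulus_roster()]).
#' @param availability optional data frame (`talker_id`, `word_id`) listing
#'   available tokens; `NULL` means every token exists.
#' @param reps presentation repetitions per token.
#' @return data frame: `participant`, `pair_id`, `word_id`, `voice_id`,
#'   `own_voice`, `group`, `repetition`.
#' @export
build_roster <- function(participant, assignments, roster = stimulus_roster(),
                         availability = NULL, reps = 4L) {
  reps <- stopifnot_scalar_count(reps, "reps")
  mine <- assignments[assignments$talker_id == participant, , drop = FALSE]
  if (!nrow(mine)) stop("participant ", participant, " absent from all assignments")
  have <- function(voice, word) {
    is.null(availability) ||
      any(availability$talker_id == voice & availability$word_id == word)
  }
  out <- vector("list", nrow(mine))
  for (i in seq_len(nrow(mine))) {
    p <- mine$pair_id[i]
    words <- unlist(roster[roster$pair_id == p, c("word_a", "word_b")])
    if (length(words) != 2L) stop("pair ", p, " not in roster")
    if (!have(participant, words[1]) || !have(participant, words[2])) next
    members <- assignments$talker_id[assignments$pair_id == p &
                                       assignments$group == mine$group[i]]
    members <- members[vapply(members, function(v)
      have(v, words[1]) && have(v, words[2]), logical(1))]
    grid <- expand.grid(word_id = unname(words), voice_id = members,
                        repetition = seq_len(reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- data.frame(participant = participant, pair_id = p, grid,
                       stringsAsFactors = FALSE)
    grid$own_voice <- grid$voice_id == participant
    grid$group <- mine$group[i]
    out[[i]] <- grid
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    stop("participant ", participant, " has no available pairs")
  }
  rownames(out) <- NULL
  out
}

#' Randomize a roster into blocks
#'
#' Uniform permutation of the roster under `seed`, split into `n_blocks`
#' contiguous blocks whose sizes differ by at most one (earlier blocks take
#' the remainder).
#'
#' @param roster from [build_roster()].
#' @param n_blocks number of blocks.
#' @param seed RNG seed.
#' @return the permuted roster with `trial_index` (1..n) and `block` columns.
#' @export
randomize_blocks <- function(roster, n_blocks = 4L, seed = 1) {
  n_blocks <- stopifnot_scalar_count(n_blocks, "n_blocks")
  n <- nrow(roster)
  if (!n) stop("empty roster")
  with_seed(seed, {
    out <- roster[sample.int(n), , drop = FALSE]
    sizes <- rep(n %/% n_blocks, n_blocks) +
      c(rep(1L, n %% n_blocks), rep(0L, n_blocks - n %% n_blocks))
    out$trial_index <- seq_len(n)
    out$block <- rep(seq_len(n_blocks), times = sizes)
    rownames(out) <- NULL
    out
  })
}

#' Score 2AFC responses
#'
#' @param trials data frame with `word_id` (intended) and `chosen_word_id`.
#' @return `trials` with a logical `correct` column (chosen == intended).
#' @export
score_trials <- function(trials) {
  stopifnot(all(c("word_id", "chosen_word_id") %in% names(trials)))
  trials$correct <- trials$chosen_word_id == trials$word_id
  trials
}

#' Remove implausibly fast and slow responses
#'
#' Keeps trials whose reaction time lies in `[low, high]` (bounds inclusive;
#' "under"/"over" are strict removal conditions).
#'
#' @param trials data frame with an `rt_ms` column.
#' @param low,high bounds in milliseconds.
#' @return list with `trials` (kept rows), `removed_fraction`, `n_removed`.
#' @export
filter_rt <- function(trials, low = 200, high = 5000) {
  if (!"rt_ms" %in% names(trials)) stop("trials must have an `rt_ms` column")
  rt <- trials$rt_ms
  if (anyNA(rt) || any(rt < 0)) stop("reaction times must be non-negative and present")
  keep <- rt >= low & rt <= high
  list(trials = trials[keep, , drop = FALSE],
       removed_fraction = mean(!keep),
       n_removed = sum(!keep))
}

#' Build the full experiment design for a cohort
#'
#' Convenience wrapper: per-participant rosters for every talker in the
#' assignments, each independently randomized into blocks.
#'
#' @param assignments stacked [assign_groups()] output for all pairs.
#' @param roster pair/word table.
#' @param availability optional availability mask (see [build_roster()]).
#' @param reps repetitions per token; `n_blocks` blocks per participant.
#' @param seed base seed; participant p uses `seed + p`.
#' @param n_blocks number of blocks.
#' @return data frame of all participants' ordered trials.
#' @export
build_experiment <- function(assignments, roster = stimulus_roster(),
                             availability = NULL, reps = 4L, n_blocks = 4L,
                             seed = 1) {
  participants <- sort(unique(assignments$talker_id))
  out <- lapply(seq_along(participants), function(i) {
    r <- build_roster(participants[i], assignments, roster, availability, reps)
    randomize_blocks(r, n_blocks = n_blocks, seed = seed + i)
  })
  do.call(rbind, out)
}
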