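#' Standardize a pair's feature vectors
#'
#' Centers and scales each of the 7 feature dimensions to mean 0 and SD 1
#' over all word-vectors of one minimal pair (both pair members, every
#' contributing talker) — the pair-local frame in which Euclidean contrast
#' distances are computed. Zero-variance dimensions map to 0.
#'
#' @param vectors feature rows (one per talker x word) for a single pair, as
#'   from [feature_table()].
#' @return `vectors` with the 7 feature columns standardized.
#' @export
zscore_features <- function(vectors) {
  num <- feature_dims()
  miss <- setdiff(num, names(vectors))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (length(unique(vectors$talker_id)) < 2L) {
    stop("at least 2 talkers must contribute to the pair")
  }
  for (d in num) {
    x <- vectors[[d]]
    s <- sd(x)
    vectors[[d]] <- if (!is.finite(s) || s == 0) rep(0, length(x)) else
      (x - mean(x)) / s
  }
  vectors
}

feature_dims <- function() {
  c("f1_c0", "f1_c1", "f1_c2", "f2_c0", "f2_c1", "f2_c2", "duration")
}

#' Euclidean distance between two standardized feature vectors
#'
#' @param vec_a,vec_b standardized 7-D vectors (numeric vectors or one-row
#'   data frames in the same pair frame).
#' @return non-negative scalar distance.
#' @export
pair_distance <- function(vec_a, vec_b) {
  a <- as_feature_vec(vec_a)
  b <- as_feature_vec(vec_b)
  if (length(a) != length(b)) stop("feature dimension mismatch")
  sqrt(sum((a - b)^2))
}

as_feature_vec <- function(v) {
  if (is.data.frame(v)) {
    v <- unlist(v[intersect(feature_dims(), names(v))])
  }
  as.numeric(v)
}

#' Per-talker, per-pair contrastiveness scores
#'
#' For each minimal pair: standardizes all contributing word-vectors in the
#' pair-local frame, computes each talker's 7-D Euclidean distance between
#' the pair's two words, and ranks talkers (rank 1 = most contrastive;
#' ties broken by talker id). Talkers missing either word are excluded from
#' that pair.
#'
#' @param features per-word feature table (see [feature_table()]).
#' @param roster pair/word table (defaults to [stimulus_roster()]).
#' @return data frame: `pair_id`, `talker_id`, `distance`, `rank`.
#' @export
contrast_scores <- function(features, roster = stimulus_roster()) {
  out <- lapply(seq_len(nrow(roster)), function(i) {
    p <- roster$pair_id[i]
    wa <- roster$word_a[i]; wb <- roster$word_b[i]
    sub <- features[features$word_id %in% c(wa, wb), , drop = FALSE]
    both <- names(which(table(unique(sub[c("talker_id", "word_id")])$talker_id) == 2L))
    sub <- sub[sub$talker_id %in% both, , drop = FALSE]
    if (length(both) < 2L) return(NULL)
    z <- zscore_features(sub)
    d <- vapply(both, function(tk) {
      pair_distance(z[z$talker_id == tk & z$word_id == wa, ][1, ],
                    z[z$talker_id == tk & z$word_id == wb, ][1, ])
    }, numeric(1))
    ord <- order(-d, both)
    rnk <- integer(length(both))
    rnk[ord] <- seq_along(ord)
    data.frame(pair_id = p, talker_id = both,
               distance = unname(d), rank = rnk)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign ranked contrastiveness groups for one pair
#'
#' Talkers are sorted by descending distance (ties broken by talker id) and
#' cut into `n_groups` contiguous blocks labelled A (most contrastive)
#' onwards, with block sizes as equal as possible: every group gets
#' `floor(n / n_groups)` talkers and the largest remainders go to the
#' earliest groups. Sizes outside `size_bounds` trigger a warning, not an
#' error. An explicit `override` table reproduces any manual regrouping.
#'
#' @param scores [contrast_scores()] rows for a single pair.
#' @param n_groups number of groups (>= 2).
#' @param size_bounds intended `(min, max)` group size.
#' @param override optional data frame (`talker_id`, `group`) taking
#'   precedence over the computed assignment.
#' @return data frame: `pair_id`, `talker_id`, `group`, `distance`, `rank`.
#' @export
assign_groups <- function(scores, n_groups = 5L, size_bounds = c(5L, 7L),
                          override = NULL) {
  n_groups <- stopifnot_scalar_count(n_groups, "n_groups", min = 2L)
  if (length(unique(scores$pair_id)) != 1L) {
    stop("assign_groups() works on the scores of a single pair")
  }
  n <- nrow(scores)
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (any(sizes < size_bounds[1] | sizes > size_bounds[2])) {
    warning(sprintf("group sizes (%s) fall outside the intended bounds [%d, %d]",
                    paste(sizes, collapse = ","), size_bounds[1], size_bounds[2]))
  }
  ord <- order(-scores$distance, scores$talker_id)
  out <- scores[ord, , drop = FALSE]
  out$group <- rep(LETTERS[seq_len(n_groups)], times = sizes)
  if (!is.null(override)) {
    idx <- match(out$talker_id, override$talker_id)
    out$group[!is.na(idx)] <- override$group[idx[!is.na(idx)]]
  }
  rownames(out) <- NULL
  out[, c("pair_id", "talker_id", "group", "distance", "rank")]
}

#' Group assignments for every pair
#'
#' @param scores stacked [contrast_scores()] for all pairs.
#' @param ... passed to [assign_groups()].
#' @return stacked assignment data frame.
#' @export
assign_groups_all <- function(scores, ...) {
  out <- lapply(split(scores, scores$pair_id), assign_groups, ...)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
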