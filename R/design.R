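#' Forward-difference contrast matrix
#'
#' Coding matrix for an ordered factor with `k` levels in which fitted
#' coefficient `j` estimates the difference between adjacent level means,
#' `mu_j - mu_(j+1)`. Column `j` carries `(k - j)/k` for levels `1..j` and
#' `-j/k` for levels `j+1..k`; columns sum to zero, so with an intercept the
#' intercept is the unweighted grand mean across levels.
#'
#' @param k number of factor levels (>= 2).
#' @return a `k x (k-1)` numeric matrix; rows named by level index.
#' @examples
#' forward_difference_matrix(5)
#' @export
forward_difference_matrix <- function(k) {
  k <- stopifnot_scalar_count(k, "k", min = 2L)
  m <- matrix(0, k, k - 1L)
  for (j in seq_len(k - 1L)) {
    m[seq_len(j), j] <- (k - j) / k
    m[(j + 1L):k, j] <- -j / k
  }
  rownames(m) <- seq_len(k)
  colnames(m) <- paste0(seq_len(k - 1L), "v", 2:k)
  m
}

#' Build the accuracy-model design matrices
#'
#' Assembles the fixed-effect design for the word-identification accuracy
#' model: intercept, Voice Match (treatment coded, other voice = reference),
#' Trial (centered and scaled to unit SD over the supplied trials),
#' Contrastiveness Group (forward-difference coded), the Voice Match x Group,
#' Trial x Group and Voice Match x Trial interactions, plus the index
#' structures used for by-participant random intercepts and slopes.
#'
#' @param trials data frame with columns `participant`, `own_voice` (logical
#'   or 0/1), `trial_index` (numeric), `group` (factor or character; levels
#'   ordered most- to least-contrastive), and optionally `correct`.
#' @param group_levels explicit level ordering; defaults to the factor levels
#'   of `trials$group` (or sorted unique values).
#' @return list with elements `X` (fixed-effect matrix, `1 + 1 + 1 + (k-1)*3
#'   + 1` columns for `k` groups), `y` (response vector or `NULL`),
#'   `participant_index`, `participants`, `re_covariates` (per-trial columns
#'   multiplying the random intercept, Voice Match slope and Trial slope),
#'   `group_levels`, `trial_center`, `trial_scale`.
#' @export
build_design <- function(trials, group_levels = NULL) {
  req <- c("participant", "own_voice", "trial_index", "group")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(group_levels)) {
    group_levels <- if (is.factor(trials$group)) levels(trials$group) else
      sort(unique(as.character(trials$group)))
  }
  g <- factor(as.character(trials$group), levels = group_levels)
  if (anyNA(g)) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(as.character(trials$group)), group_levels), collapse = ", "))
  }
  k <- length(group_levels)
  own <- as.numeric(trials$own_voice)
  if (!all(own %in% c(0, 1))) stop("own_voice must be logical or 0/1")
  tr_raw <- as.numeric(trials$trial_index)
  mu <- mean(tr_raw); s <- sd(tr_raw)
  if (!is.finite(s) || s == 0) stop("trial_index has no variation; cannot scale")
  tr <- (tr_raw - mu) / s

  fd <- forward_difference_matrix(k)
  G <- fd[as.integer(g), , drop = FALSE]
  gnm <- paste0(group_levels[-k], "v", group_levels[-1])
  colnames(G) <- gnm
  X <- cbind(
    "(Intercept)" = 1, own = own, trial = tr, G,
    `colnames<-`(G * own, paste0("own:", gnm)),
    `colnames<-`(G * tr, paste0("trial:", gnm)),
    "own:trial" = own * tr
  )
  participants <- sort(unique(as.character(trials$participant)))
  pid <- match(as.character(trials$participant), participants)
  list(
    X = X,
    y = if ("correct" %in% names(trials)) as.numeric(trials$correct) else NULL,
    participant_index = pid,
    participants = participants,
    re_covariates = cbind(intercept = 1, own = own, trial = tr),
    group_levels = group_levels,
    trial_center = mu,
    trial_scale = s
  )
}
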