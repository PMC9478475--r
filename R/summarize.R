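#' Posterior summaries in the reporting format of the accuracy model
#'
#' Median, posterior mean, equal-tailed 95% credible interval and probability
#' of direction per parameter, plus the evidence flags used to read the
#' model: an effect is *compelling* when the 95% CrI excludes zero, and has
#' *weak evidence* when the CrI includes zero but the probability of
#' direction is at least 0.95.
#'
#' @param fit an `ownvoice_fit`, or an iterations x chains x parameters draw
#'   array, or a draws matrix (draws x parameters).
#' @param parameters optional character vector selecting parameters.
#' @return data frame with columns `parameter`, `median`, `mean`, `cri_low`,
#'   `cri_high`, `pd`, `compelling`, `weak_evidence`.
#' @export
summarize_posterior <- function(fit, parameters = NULL) {
  m <- draws_matrix(fit)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, colnames(m))
    if (length(missing)) stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    m <- m[, parameters, drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no posterior draws to summarize")
  out <- lapply(colnames(m), function(p) {
    d <- m[, p]
    q <- unname(quantile(d, c(0.025, 0.5, 0.975), names = FALSE, type = 7))
    pd <- max(mean(d > 0), mean(d < 0))
    pd <- max(pd, 0.5)
    data.frame(parameter = p, median = q[2], mean = mean(d),
               cri_low = q[1], cri_high = q[3], pd = pd,
               compelling = q[1] > 0 || q[3] < 0,
               weak_evidence = !(q[1] > 0 || q[3] < 0) && pd >= 0.95)
  })
  do.call(rbind, out)
}

#' Flatten posterior draws to a matrix
#'
#' @param fit an `ownvoice_fit`, a 3-d draw array, or a matrix.
#' @return draws x parameters matrix with all chains stacked.
#' @export
draws_matrix <- function(fit) {
  if (inherits(fit, "ownvoice_fit")) fit <- fit$draws
  if (is.matrix(fit)) return(fit)
  if (length(dim(fit)) == 3L) {
    d <- dim(fit)
    m <- matrix(aperm(fit, c(1, 2, 3)), d[1] * d[2], d[3])
    colnames(m) <- dimnames(fit)[[3]]
    return(m)
  }
  m <- matrix(as.numeric(fit), ncol = 1)
  colnames(m) <- "parameter"
  m
}
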