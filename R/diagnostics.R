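# Convergence diagnostics: rank-normalized split R-hat and bulk ESS
# (Vehtari, Gelman, Simpson, Carpenter & Burkner 2021).

# draws: iterations x chains matrix -> split into 2*chains half-chains
split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  cm <- colMeans(m)
  B <- n * var(cm)
  W <- mean(apply(m, 2, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer initial-monotone-sequence ESS on (already split) chains
ess_basic <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (n < 4L) return(NA_real_)
  cm <- colMeans(m)
  B <- n * var(cm)
  cv <- apply(m, 2, var)
  W <- mean(cv)
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  # per-chain autocovariance via FFT
  acov <- sapply(seq_len(nc), function(j) {
    x <- m[, j] - cm[j]
    nfft <- 2^ceiling(log2(2 * n))
    f <- fft(c(x, rep(0, nfft - n)))
    ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
    ac / ac[1] * cv[j] * (n - 1) / n
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # paired sums, initial monotone positive sequence
  tau <- -1
  prev <- Inf
  t <- 1L
  while (t + 1L < n) {
    p <- rho[t + 1L] + if (t + 2L <= n) rho[t + 2L] else 0
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
    t <- t + 2L
  }
  tau <- max(tau + 1 + rho[1], 1 / log10(n * nc))  # tau >= small floor
  min(n * nc / tau, n * nc)
}

#' Split R-hat and bulk ESS for an array of posterior draws
#'
#' Rank-normalized split R-hat and bulk effective sample size per parameter.
#'
#' @param draws iterations x chains x parameters array (or iterations x
#'   chains matrix for a single parameter).
#' @return data frame with columns `parameter`, `rhat`, `bulk_ess`.
#' @export
fit_diagnostics <- function(draws) {
  if (length(dim(draws)) == 2L) {
    draws <- array(draws, c(dim(draws), 1L),
                   dimnames = list(NULL, NULL, "parameter"))
  }
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- paste0("par", seq_len(dim(draws)[3]))
  res <- lapply(seq_len(dim(draws)[3]), function(i) {
    m <- split_chains(matrix(draws[, , i], dim(draws)[1], dim(draws)[2]))
    z <- rank_normalize(m)
    c(rhat = rhat_basic(z), bulk_ess = ess_basic(z))
  })
  out <- do.call(rbind, res)
  data.frame(parameter = pn, rhat = out[, "rhat"], bulk_ess = out[, "bulk_ess"],
             row.names = NULL)
}
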