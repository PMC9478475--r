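#' @useDynLib ownvoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx dt fft median qnorm quantile rbinom
#'   rexp rlnorm rnorm runif runmed sd setNames toeplitz var plogis qlogis
#' @importFrom utils head read.csv read.delim write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Multivariate normal draws via Cholesky (n x d).
rmvnorm_chol <- function(n, sigma) {
  d <- nrow(sigma)
  z <- matrix(rnorm(n * d), n, d)
  z %*% chol(sigma)
}

# root-mean-square amplitude
rms <- function(x) sqrt(mean(x^2))
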