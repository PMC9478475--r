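#' Priors for the accuracy model
#'
#' Weakly informative defaults: Normal(0, 5) on the intercept, Normal(0, 2.5)
#' on all other population-level coefficients, half-Student-t(3, 0, 2.5) on
#' the random-effect standard deviations, and LKJ(2) on the 3x3 by-participant
#' random-effect correlation matrix.
#'
#' @param intercept_sd,coef_sd prior SDs of the normal priors on the intercept
#'   and remaining fixed effects (log-odds scale).
#' @param re_sd_scale,re_sd_df scale and df of the half-Student-t prior on
#'   random-effect SDs.
#' @param lkj_eta shape of the LKJ prior on the random-effect correlations.
#' @return list of prior settings.
#' @export
accuracy_priors <- function(intercept_sd = 5, coef_sd = 2.5,
                            re_sd_scale = 2.5, re_sd_df = 3, lkj_eta = 2) {
  stopifnot(intercept_sd > 0, coef_sd > 0, re_sd_scale > 0, re_sd_df > 0,
            lkj_eta > 0)
  list(intercept_sd = intercept_sd, coef_sd = coef_sd,
       re_sd_scale = re_sd_scale, re_sd_df = re_sd_df, lkj_eta = lkj_eta)
}

# --- spherical-Cholesky correlation parameterization ------------------------
# L is lower triangular with unit rows; R = L L' is a correlation matrix.
# Under LKJ(2) the three cosines have independent scaled-Beta priors:
# (c12+1)/2, (c13+1)/2 ~ Beta(2.5, 2.5); (c23+1)/2 ~ Beta(2, 2).
chol_from_cosines <- function(cc) {
  c12 <- cc[1]; c13 <- cc[2]; c23 <- cc[3]
  s12 <- sqrt(1 - c12^2); s13 <- sqrt(1 - c13^2); s23 <- sqrt(1 - c23^2)
  matrix(c(1, 0, 0,
           c12, s12, 0,
           c13, s13 * c23, s13 * s23), 3, 3, byrow = TRUE)
}

# log prior density of the cosines implied by LKJ(eta) in d = 3
lkj_cosine_logprior <- function(cc, eta) {
  e <- eta - 1
  (e + 0.5) * (log1p(-cc[1]^2) + log1p(-cc[2]^2)) + e * log1p(-cc[3]^2)
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice1 <- function(x0, logf, w = 0.5, lower = -Inf, upper = Inf, max_steps = 30L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  y <- f0 - rexp(1)
  l <- x0 - runif(1) * w
  r <- l + w
  k <- max_steps
  while (k > 0 && l > lower && logf(l) > y) { l <- l - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && r < upper && logf(r) > y) { r <- r + w; k <- k - 1 }
  l <- max(l, lower); r <- min(r, upper)
  repeat {
    x1 <- runif(1, l, r)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# log-density of (u | sd, cosines) plus hyperpriors, up to a constant.
# Su = crossprod(U), S = number of participants.
re_hyper_logpost <- function(log_sd, cc, Su, S, priors) {
  sdv <- exp(log_sd)
  L <- chol_from_cosines(cc)
  DL <- sdv * L                       # row scaling: chol factor of Sigma
  dg <- diag(DL)
  if (any(dg <= 0)) return(-Inf)
  # tr(Sigma^{-1} Su) via forward solve against the factor
  V <- forwardsolve(DL, diag(3))
  qf <- sum((V %*% Su) * V)           # tr(V Su V') = tr(Sigma^-1 Su)
  ll <- -S * sum(log(dg)) - 0.5 * qf
  lp_sd <- sum(dt(sdv / priors$re_sd_scale, df = priors$re_sd_df, log = TRUE)) +
    sum(log_sd)                       # Jacobian of the log transform
  ll + lp_sd + lkj_cosine_logprior(cc, priors$lkj_eta)
}

#' Fit the Bayesian multilevel accuracy model
#'
#' Bernoulli-logit multilevel regression of trial-level correctness on Voice
#' Match, Trial and Contrastiveness Group (with the Voice Match x Group,
#' Trial x Group and Voice Match x Trial interactions), with correlated
#' by-participant random intercepts and Voice Match / Trial slopes. Sampling
#' is by a Polya-Gamma auxiliary-variable Gibbs sampler: all fixed and random
#' coefficients are drawn jointly from their full conditional multivariate
#' normal, and the random-effect SDs and correlations by slice sampling under
#' half-Student-t and LKJ priors.
#'
#' @param trials RT-filtered trial data frame (see [build_design()]); must
#'   contain a `correct` column.
#' @param priors from [accuracy_priors()].
#' @param chains number of chains.
#' @param iter total iterations per chain, including warm-up.
#' @param warmup warm-up iterations discarded per chain.
#' @param seed RNG seed (one stream; chains are drawn sequentially).
#' @param group_levels optional explicit group level order.
#' @param design optionally, a prebuilt design list from [build_design()]
#'   (with non-NULL `y`); `trials` is ignored when supplied.
#' @param sample_prior draw from the prior instead of the posterior (exact
#'   independent draws; the data are used only for the design shape).
#' @return an object of class `ownvoice_fit`: list with `draws` (iterations x
#'   chains x parameters array of post-warmup draws), `parameters`,
#'   `diagnostics` (split R-hat and bulk ESS per parameter; see
#'   [fit_diagnostics()]), `design`, and the sampler configuration.
#' @export
fit_accuracy_model <- function(trials, priors = accuracy_priors(), chains = 4,
                               iter = 4000, warmup = 1000, seed = 1,
                               group_levels = NULL, design = NULL,
                               sample_prior = FALSE) {
  chains <- stopifnot_scalar_count(chains, "chains")
  iter <- stopifnot_scalar_count(iter, "iter")
  warmup <- stopifnot_scalar_count(warmup, "warmup", min = 0L)
  if (warmup >= iter) stop("warmup must be smaller than iter")
  d <- if (is.null(design)) build_design(trials, group_levels) else design
  if (is.null(d$y)) stop("trials must contain a `correct` column")
  if (!all(d$y %in% c(0, 1))) stop("`correct` must be 0/1")

  X <- d$X
  y <- d$y
  pid <- d$participant_index
  C <- d$re_covariates
  P <- ncol(X)
  S <- length(d$participants)
  N <- nrow(X)
  prior_prec <- c(1 / priors$intercept_sd^2, rep(1 / priors$coef_sd^2, P - 1L))
  kappa <- y - 0.5
  ysign <- 2 * y - 1
  b_fixed <- as.vector(crossprod(X, kappa))
  b_re <- matrix(0, S, 3)
  for (k in 1:3) b_re[, k] <- rowsum_by(kappa * C[, k], pid, S)
  u_cols <- P + rep((seq_len(S) - 1L) * 3L, each = 3L) + rep(1:3, S)
  # constant products for the grouped sufficient statistics (j,k in upper tri)
  Cjk <- cbind(1, C[, 2], C[, 3], C[, 2]^2, C[, 2] * C[, 3], C[, 3]^2)
  jk_rows <- c(1L, 1L, 1L, 2L, 2L, 3L)
  jk_cols <- c(1L, 2L, 3L, 2L, 3L, 3L)

  par_names <- c(colnames(X), paste0("sd_u[", 1:3, "]"),
                 c("cor_u[1,2]", "cor_u[1,3]", "cor_u[2,3]"),
                 paste0("u[", rep(seq_len(S), each = 3L), ",", rep(1:3, S), "]"))
  n_save <- iter - warmup
  draws <- array(NA_real_, c(n_save, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  if (sample_prior) {
    eta_lkj <- priors$lkj_eta
    draws <- with_seed(seed, {
      for (ch in seq_len(chains)) for (it in seq_len(n_save)) {
        beta <- rnorm(P, 0, c(priors$intercept_sd, rep(priors$coef_sd, P - 1L)))
        sdv <- abs(stats::rt(3, priors$re_sd_df)) * priors$re_sd_scale
        cc <- c(2 * stats::rbeta(2, eta_lkj + 0.5, eta_lkj + 0.5) - 1,
                2 * stats::rbeta(1, eta_lkj, eta_lkj) - 1)
        L <- chol_from_cosines(cc)
        Rm <- tcrossprod(L)
        U <- rmvnorm_chol(S, (sdv %o% sdv) * Rm)
        draws[it, ch, ] <- c(beta, sdv, Rm[c(2L, 3L, 6L)], as.vector(t(U)))
      }
      draws
    })
    diags <- fit_diagnostics(draws[, , seq_len(P + 6L), drop = FALSE])
    return(structure(list(draws = draws, parameters = par_names,
                          diagnostics = diags,
                          design = d[setdiff(names(d), c("X", "y"))],
                          config = list(chains = chains, iter = iter,
                                        warmup = warmup, seed = seed,
                                        priors = priors, sample_prior = TRUE)),
                     class = "ownvoice_fit"))
  }

  with_seed(seed, {
    for (ch in seq_len(chains)) {
      beta <- rnorm(P, 0, 0.3)
      U <- matrix(0, S, 3)
      log_sd <- log(runif(3, 0.3, 1))
      mh_scale <- rep(0.4, 3)
      cc <- runif(3, -0.3, 0.3)
      for (it in seq_len(iter)) {
        # 1. Polya-Gamma auxiliaries
        eta <- as.vector(X %*% beta) + rowSums(U[pid, , drop = FALSE] * C)
        om <- .rpg1_vec(eta)
        # 2. joint draw of (beta, u) from the Gaussian full conditional
        sdv <- exp(log_sd)
        DL <- sdv * chol_from_cosines(cc)
        Tau_u <- chol2inv(chol(tcrossprod(DL)))
        Q <- matrix(0, P + 3L * S, P + 3L * S)
        sw <- sqrt(om)
        Q[1:P, 1:P] <- crossprod(X * sw) + diag(prior_prec, P)
        W <- X * om
        agg <- rowsum_by_mat(cbind(W, W * C[, 2], W * C[, 3], om * Cjk),
                             pid, S)                  # one grouped pass
        for (k in 1:3) {
          Q[1:P, P + (seq_len(S) - 1L) * 3L + k] <-
            t(agg[, ((k - 1L) * P + 1L):(k * P), drop = FALSE])
        }
        for (m in 1:6) {
          rows <- P + (seq_len(S) - 1L) * 3L + jk_rows[m]
          cols <- P + (seq_len(S) - 1L) * 3L + jk_cols[m]
          Q[cbind(rows, cols)] <- agg[, 3L * P + m] + Tau_u[jk_rows[m], jk_cols[m]]
        }
        Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
        b <- c(b_fixed, as.vector(t(b_re)))
        R <- chol(Q)
        m <- backsolve(R, backsolve(R, b, transpose = TRUE))
        theta <- m + backsolve(R, rnorm(P + 3L * S))
        beta <- theta[1:P]
        U <- matrix(theta[u_cols], S, 3, byrow = TRUE)
        # 3. random-effect hyperparameters by slice sampling
        Su <- crossprod(U)
        for (dpar in 1:3) {
          log_sd[dpar] <- slice1(log_sd[dpar], function(v) {
            ls <- log_sd; ls[dpar] <- v
            re_hyper_logpost(ls, cc, Su, S, priors)
          }, w = 0.5)
        }
        for (dpar in 1:3) {
          cc[dpar] <- slice1(cc[dpar], function(v) {
            cv <- cc; cv[dpar] <- v
            re_hyper_logpost(log_sd, cv, Su, S, priors)
          }, w = 0.4, lower = -1 + 1e-9, upper = 1 - 1e-9)
        }
        # 4. interweaving: re-draw the RE scales in the non-centered frame
        # (PG auxiliaries are marginalized here and redrawn at the top of the
        # next iteration), which decouples small scales from their effects.
        # One adaptive Metropolis proposal per scale; eta updates are axpys.
        L <- chol_from_cosines(cc)
        z <- forwardsolve(exp(log_sd) * L, t(U))   # 3 x S standard coords
        V <- t(L %*% z)                            # unscaled RE components
        G <- V[pid, , drop = FALSE] * C            # per-trial RE bases
        eta_base <- as.vector(X %*% beta) + as.vector(G %*% exp(log_sd))
        lp_sd <- function(v, g, sd_cur) {
          .bern_loglik_delta(eta_base, g, exp(v) - sd_cur, ysign) +
            dt(exp(v) / priors$re_sd_scale, df = priors$re_sd_df, log = TRUE) + v
        }
        for (dpar in 1:3) {
          g <- G[, dpar]
          sd_cur <- exp(log_sd[dpar])
          f_cur <- lp_sd(log_sd[dpar], g, sd_cur)
          prop <- log_sd[dpar] + rnorm(1, 0, mh_scale[dpar])
          acc <- (lp_sd(prop, g, sd_cur) - f_cur) > -rexp(1)
          if (acc) {
            eta_base <- eta_base + (exp(prop) - sd_cur) * g
            log_sd[dpar] <- prop
          }
          if (it <= warmup) {  # Robbins-Monro toward 44% acceptance
            mh_scale[dpar] <- exp(log(mh_scale[dpar]) +
                                    (as.numeric(acc) - 0.44) / sqrt(it))
          }
        }
        U <- t((exp(log_sd) * L) %*% z)
        if (it > warmup) {
          L <- chol_from_cosines(cc)
          Rm <- tcrossprod(L)
          draws[it - warmup, ch, ] <- c(beta, exp(log_sd),
                                        Rm[c(2L, 3L, 6L)],
                                        as.vector(t(U)))
        }
      }
    }
  })
  diag_idx <- seq_len(P + 6L)
  diags <- fit_diagnostics(draws[, , diag_idx, drop = FALSE])
  structure(list(draws = draws, parameters = par_names, diagnostics = diags,
                 design = d[setdiff(names(d), c("X", "y"))],
                 config = list(chains = chains, iter = iter, warmup = warmup,
                               seed = seed, priors = priors)),
            class = "ownvoice_fit")
}

# grouped sums over participants 1..S (rowsum() drops empty groups; these
# keep the full participant dimension and stay vectorized)
rowsum_by <- function(x, pid, S) {
  out <- numeric(S)
  agg <- rowsum(x, pid)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

rowsum_by_mat <- function(x, pid, S) {
  out <- matrix(0, S, ncol(x))
  agg <- rowsum(x, pid)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' @export
print.ownvoice_fit <- function(x, ...) {
  cfg <- x$config
  cat("ownvoice accuracy-model fit (Polya-Gamma Gibbs)\n")
  cat(sprintf("  %d chains x %d iterations (%d warm-up): %d post-warmup draws\n",
              cfg$chains, cfg$iter, cfg$warmup,
              cfg$chains * (cfg$iter - cfg$warmup)))
  cat(sprintf("  max split R-hat %.3f, min bulk ESS %.0f (%s)\n",
              max(x$diagnostics$rhat), min(x$diagnostics$bulk_ess),
              if (converged(x)) "converged" else "NOT converged"))
  invisible(x)
}

#' Convergence check
#'
#' A fit is declared converged iff every monitored split R-hat is below 1.01.
#' @param fit an `ownvoice_fit`.
#' @return logical scalar.
#' @export
converged <- function(fit) {
  all(fit$diagnostics$rhat < 1.01, na.rm = TRUE)
}
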