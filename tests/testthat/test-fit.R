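test_that("Polya-Gamma draws match series-expansion moments", {
  with_seed_local(21, {
    for (z in c(0, 0.8, 2.5, 8)) {
      x <- ownvoice:::.rpg1_vec(rep(z, 40000))
      mom <- pg_moment_oracle(z)
      expect_equal(mean(x), unname(mom["mean"]), tolerance = 0.01)
      expect_equal(var(x), unname(mom["var"]), tolerance = 0.04)
      # closed form for the mean as a second, independent reference
      m_cf <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
      expect_equal(mean(x), m_cf, tolerance = 0.01)
    }
  })
})

test_that("posterior medians agree with a maximum-likelihood fit at scale", {
  des <- toy_design(S = 12, npt = 400, seed = 22)
  beta <- c(1.2, 0.3, 0.1, -0.2, 0.25, 0.2, 0.25, rep(0, 8), 0.05)
  tr <- simulate_from_beta(des, beta, re_sd = c(0.3, 0.2, 0.1), seed = 23)
  fit <- fit_accuracy_model(tr, chains = 2, iter = 900, warmup = 300, seed = 24)
  s <- summarize_posterior(fit, parameters = c("(Intercept)", "own", "trial"))
  g <- glm(tr$correct ~ build_design(tr)$X - 1, family = binomial)
  expect_lt(abs(s$median[2] - coef(g)[2]), 0.08)
  expect_lt(abs(s$median[3] - coef(g)[3]), 0.05)
  # generating values inside their 95% intervals
  expect_true(s$cri_low[2] < 0.3 && 0.3 < s$cri_high[2])
})

test_that("the Gibbs engine matches an independent MCMC implementation", {
  skip_if_not_installed("rjags")
  des <- toy_design(S = 8, npt = 200, seed = 25)
  beta <- c(1.0, 0.4, 0.1, rep(0, 12), 0)
  tr <- simulate_from_beta(des, beta, re_sd = c(0.4, 0.2, 0.1), seed = 26)
  fit <- fit_accuracy_model(tr, chains = 2, iter = 1500, warmup = 500, seed = 27)
  s <- summarize_posterior(fit, parameters = c("(Intercept)", "own", "trial",
                                               "sd_u[1]"))
  d <- build_design(tr)
  jm_str <- "
  model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- mu[i] + u[pid[i],1] + u[pid[i],2]*own[i] + u[pid[i],3]*tr[i]
    }
    mu <- X %*% beta
    beta[1] ~ dnorm(0, 0.04)
    for (j in 2:P) { beta[j] ~ dnorm(0, 0.16) }
    for (s in 1:S) { u[s,1:3] ~ dmnorm(zero3, Tau) }
    for (k in 1:3) { sd_u[k] ~ dt(0, 0.16, 3) T(0,) }
    b12 ~ dbeta(2.5, 2.5); b13 ~ dbeta(2.5, 2.5); b23 ~ dbeta(2, 2)
    c12 <- 2*b12-1; c13 <- 2*b13-1; c23 <- 2*b23-1
    s12 <- sqrt(1-c12*c12); s13 <- sqrt(1-c13*c13); s23 <- sqrt(1-c23*c23)
    L[1,1] <- 1;   L[1,2] <- 0;       L[1,3] <- 0
    L[2,1] <- c12; L[2,2] <- s12;     L[2,3] <- 0
    L[3,1] <- c13; L[3,2] <- s13*c23; L[3,3] <- s13*s23
    R <- L %*% t(L)
    for (a in 1:3) { for (b in 1:3) { Sigma[a,b] <- R[a,b]*sd_u[a]*sd_u[b] } }
    Tau <- inverse(Sigma)
  }"
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(jm_str),
    data = list(N = nrow(d$X), P = ncol(d$X), S = length(d$participants),
                X = d$X, y = d$y, pid = d$participant_index,
                own = d$re_covariates[, "own"], tr = d$re_covariates[, "trial"],
                zero3 = rep(0, 3)),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  js <- rjags::coda.samples(jm, c("beta", "sd_u"), n.iter = 2000)
  jmat <- do.call(rbind, lapply(js, as.matrix))
  ref <- c(median(jmat[, "beta[1]"]), median(jmat[, "beta[2]"]),
           median(jmat[, "beta[3]"]), median(jmat[, "sd_u[1]"]))
  expect_equal(s$median, ref, tolerance = 0.15, ignore_attr = TRUE)
  expect_lt(max(abs(s$median[1:3] - ref[1:3])), 0.1)
})

test_that("prior-predictive intercept interval spans at least [-8, 8]", {
  des <- toy_design(S = 5, npt = 40, seed = 28)
  des$correct <- 1L
  fit <- fit_accuracy_model(des, chains = 2, iter = 2100, warmup = 100,
                            seed = 29, sample_prior = TRUE)
  s <- summarize_posterior(fit, parameters = "(Intercept)")
  expect_lt(s$cri_low, -8)
  expect_gt(s$cri_high, 8)
  # correlation draws respect the LKJ(2) marginal: mean 0, sd = 1/sqrt(2e+2)
  m <- draws_matrix(fit)
  r <- m[, "cor_u[1,2]"]
  expect_lt(abs(mean(r)), 0.03)
  expect_equal(sd(r), sqrt(1 / 6), tolerance = 0.05)
})

test_that("posterior summaries report median, CrI, pd and evidence flags", {
  m <- matrix(rep(0.7, 500), ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_posterior(m)
  expect_equal(s$median, 0.7)
  expect_equal(s$cri_low, 0.7)
  expect_equal(s$pd, 1)
  expect_true(s$compelling)
  with_seed_local(30, sym <- matrix(rnorm(12000), ncol = 1,
                                    dimnames = list(NULL, "x")))
  ssym <- summarize_posterior(sym)
  expect_lt(ssym$pd, 0.55)
  expect_false(ssym$compelling)
  expect_false(ssym$weak_evidence)
  with_seed_local(31, d <- matrix(rnorm(12000, 0.23, 0.09), ncol = 1,
                                  dimnames = list(NULL, "own")))
  sd_ <- summarize_posterior(d)
  expect_equal(sd_$pd, pnorm(0.23 / 0.09), tolerance = 0.004)
  expect_error(summarize_posterior(d, parameters = "nope"), "unknown parameter")
})

test_that("split R-hat flags disagreeing chains and passes mixed ones", {
  with_seed_local(32, {
    good <- array(rnorm(4000 * 4), c(4000, 4, 1),
                  dimnames = list(NULL, NULL, "x"))
    bad <- good
    bad[, 2, 1] <- bad[, 2, 1] + 1.5
  })
  dg <- fit_diagnostics(good)
  db <- fit_diagnostics(bad)
  expect_lt(dg$rhat, 1.01)
  expect_gt(dg$bulk_ess, 1000)
  expect_gt(db$rhat, 1.2)
})

test_that("converged() applies the R-hat < 1.01 rule", {
  f <- structure(list(diagnostics = data.frame(rhat = c(1.001, 1.005))),
                 class = "ownvoice_fit")
  expect_true(converged(f))
  f$diagnostics$rhat[2] <- 1.02
  expect_false(converged(f))
})
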