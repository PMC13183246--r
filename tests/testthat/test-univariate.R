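test_that("univariate sampler recovers known variance components", {
  ds <- make_mixed_data(N = 200L, T = 4L, s2u = 4, s2e = 1, seed = 7L)
  design <- build_design(ds)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 1500L, burn_in = 500L,
                     thin = 2L, seed = 3L)
  fit <- fit_univariate(design, "met1", cfg)
  expect_lt(abs(mean(fit$sigma2_u_draws) - 4) / 4, 0.15)
  expect_lt(abs(mean(fit$sigma2_e_draws) - 1) / 1, 0.15)
  expect_true(all(fit$sigma2_u_draws > 0))
  expect_true(all(fit$sigma2_e_draws > 0))
  # summaries recomputable from the pooled draws
  expect_equal(fit$summaries$beta_mean, colMeans(fit$beta_draws))
  expect_equal(fit$summaries$beta_var, apply(fit$beta_draws, 2L, var))
  expect_equal(fit$summaries$sigma2_u_mean, mean(fit$sigma2_u_draws))
})

test_that("flat-prior, fixed-variance posterior mean matches the GLS oracle", {
  ds <- make_mixed_data(N = 150L, T = 4L, s2u = 4, s2e = 1, seed = 9L)
  design <- build_design(ds)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 3000L, burn_in = 500L,
                     thin = 1L, seed = 5L)
  fit <- fit_univariate(design, "met1", cfg,
                        hyper = list(beta_mean = 0, beta_var = 1e10),
                        fixed = list(sigma2_u = 4, sigma2_e = 1))

  # direct GLS with the known variance components, blocked by individual
  y <- design$Y[, 1L]; X <- design$X
  A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
  for (i in seq_len(design$N)) {
    rows <- which(design$id_index == i)
    Vi <- 4 * matrix(1, length(rows), length(rows)) + diag(1, length(rows))
    Vinv <- solve(Vi)
    A <- A + t(X[rows, , drop = FALSE]) %*% Vinv %*% X[rows, , drop = FALSE]
    b <- b + t(X[rows, , drop = FALSE]) %*% Vinv %*% y[rows]
  }
  beta_gls <- solve(A, b)

  for (p in seq_len(ncol(X))) {
    se <- batch_se(fit$beta_draws[, p])
    expect_lt(abs(mean(fit$beta_draws[, p]) - beta_gls[p]), 3 * se)
  }
})

test_that("independent fits are deterministic and independent across metabolites", {
  ds <- make_mixed_data(N = 40L, T = 4L, M = 2L, seed = 13L)
  design <- build_design(ds)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 1100L, burn_in = 100L,
                     thin = 1L, seed = 21L)
  fit1 <- fit_independent_model(design, cfg)
  fit2 <- fit_independent_model(design, cfg)
  expect_identical(fit1$fits[["met1"]]$beta_draws,
                   fit2$fits[["met1"]]$beta_draws)
  expect_identical(fit1$fits[["met2"]]$sigma2_e_draws,
                   fit2$fits[["met2"]]$sigma2_e_draws)

  # cross-metabolite correlation of posterior-predictive replicates ~ 0
  pred <- predictive_draws(fit1, design, seed = 2L)
  cors <- vapply(seq_len(min(40L, dim(pred$draws)[2L])), function(ci)
    cor(pred$draws[, ci, 1L], pred$draws[, ci, 2L]), 0)
  expect_lt(abs(mean(cors)), 0.05)

  # M = 1 reduces to a single univariate fit
  ds1 <- make_mixed_data(N = 30L, T = 4L, M = 1L, seed = 14L)
  de1 <- build_design(ds1)
  ind1 <- fit_independent_model(de1, cfg)
  cfg1 <- cfg
  cfg1$seed <- metaboflag:::derive_seed(cfg$seed, 0L) + 1000L
  solo <- fit_univariate(de1, "met1", cfg1)
  expect_identical(ind1$fits[["met1"]]$beta_draws, solo$beta_draws)
})

test_that("prior summaries stack correctly and are permutation-equivariant", {
  ds <- make_mixed_data(N = 30L, T = 4L, M = 2L, seed = 3L)
  design <- build_design(ds)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 400L, burn_in = 100L, thin = 1L,
                     seed = 2L)
  fit <- fit_independent_model(design, cfg)
  sm <- summarize_for_prior(fit)
  expect_equal(colnames(sm$beta_mean), c("met1", "met2"))
  expect_equal(sm$beta_mean[, "met1"], fit$fits[["met1"]]$summaries$beta_mean)
  expect_equal(sm$sigma2_e[["met2"]],
               mean(fit$fits[["met2"]]$sigma2_e_draws))

  sm_rev <- summarize_for_prior(rev(fit$fits))
  expect_equal(sm_rev$beta_mean[, c("met1", "met2")], sm$beta_mean)
  expect_equal(sm_rev$sigma2_u[c("met1", "met2")], sm$sigma2_u)

  # mismatched covariate structures are rejected
  broken <- fit$fits
  broken[[2L]]$covariates <- c("(Intercept)", "other")
  expect_error(summarize_for_prior(broken), "mismatched covariate")
})

test_that("inverse-Wishart generator has the analytic mean", {
  # 1-D: IW(s, nu) = inverse-gamma, mean s / (nu - 2)
  set.seed(8)
  d1 <- replicate(4000L, metaboflag:::riwish_cpp(matrix(3), 6)[1L, 1L])
  expect_lt(abs(mean(d1) - 3 / 4), 3 * sd(d1) / sqrt(length(d1)))

  # 3-D diagonal elements: mean Sigma_ii / (nu - M - 1)
  S3 <- diag(c(2, 3, 4)); S3[S3 == 0] <- 0.3
  nu <- 10
  draws <- replicate(3000L, diag(metaboflag:::riwish_cpp(S3, nu)))
  for (k in 1:3) {
    m_k <- diag(S3)[k] / (nu - 3 - 1)
    expect_lt(abs(mean(draws[k, ]) - m_k),
              3 * sd(draws[k, ]) / sqrt(ncol(draws)))
  }
})
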