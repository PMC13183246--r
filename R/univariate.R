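#' MCMC sampler settings
#'
#' Defaults follow the reference protocol: four chains of 5000 iterations,
#' a 2000-iteration burn-in and a thinning rate of 3, giving 1000 retained
#' draws per chain.
#'
#' @param n_chains Number of independent chains (>= 1; convergence
#'   diagnostics require >= 2).
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded from each chain.
#' @param thin Thinning rate.
#' @param seed Master seed; chain- and metabolite-level streams are derived
#'   from it deterministically.
#' @return An `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 5000L, burn_in = 2000L,
                        thin = 3L, seed = 1L) {
  stopifnot(n_chains >= 1L, n_iter >= 1L, burn_in >= 0L, burn_in < n_iter,
            thin >= 1L)
  S <- (n_iter - burn_in) %/% thin
  if (S < 50L)
    stop(sprintf("only %d retained draws per chain; need at least 50", S),
         call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), n_retained = as.integer(S)),
            class = "mcmc_config")
}

default_uni_hyper <- function(y) {
  vy <- var(y)
  list(beta_mean = 0, beta_var = 1e8 * vy,
       var_shape = 0.001, var_rate = 0.001 * vy)
}

#' Fit the univariate Bayesian random-intercept model for one metabolite
#'
#' Gibbs sampler for `y_itm = x_it' beta_m + u_im + e_itm` with
#' `u ~ N(0, sigma2_u)` and `e ~ N(0, sigma2_e)`. Priors are weakly
#' informative and scale-aware by default: each coefficient is
#' `N(0, 1e8 * var(y))` and both variance components are inverse-gamma with
#' shape 0.001 and rate `0.001 * var(y)`. Chains start from the ordinary
#' least-squares coefficient estimate with `u = 0` and each variance at half
#' the sample variance, so runs are deterministic given the seed.
#'
#' @param design A [build_design()] result.
#' @param metabolite Metabolite (column) name.
#' @param config An [mcmc_config()].
#' @param hyper Optional prior overrides: a list with any of `beta_mean`,
#'   `beta_var` (scalar or per-coefficient), `var_shape`, `var_rate`
#'   (shared by both variance components unless given as
#'   `u_shape`/`u_rate`/`e_shape`/`e_rate`).
#' @param fixed Optional list fixing `sigma2_u` and/or `sigma2_e` at known
#'   values (used for conditional-correctness checks).
#' @return A `univariate_posterior` with pooled post-burn-in draws
#'   (`beta_draws`, `u_draws`, `sigma2_u_draws`, `sigma2_e_draws`), the
#'   per-chain draws, and posterior `summaries`.
#' @export
fit_univariate <- function(design, metabolite, config = mcmc_config(),
                           hyper = NULL, fixed = list()) {
  stopifnot(inherits(design, "design_matrices"),
            inherits(config, "mcmc_config"))
  m <- match(metabolite, design$metabolites)
  if (is.na(m)) stop(sprintf("unknown metabolite '%s'", metabolite),
                     call. = FALSE)
  y <- design$Y[, m]
  X <- design$X
  P <- ncol(X)
  tab <- table(design$id_index)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 individuals with at least 2 observations",
         call. = FALSE)

  h <- default_uni_hyper(y)
  h[names(hyper)] <- hyper
  beta0 <- rep_len(h$beta_mean, P)
  Bdiag <- rep_len(h$beta_var, P)
  a_u <- h$u_shape %||% h$var_shape; b_u <- h$u_rate %||% h$var_rate
  a_e <- h$e_shape %||% h$var_shape; b_e <- h$e_rate %||% h$var_rate

  beta_init <- qr.solve(X, y)
  vy <- var(y)
  chains <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, cc))
    chains[[cc]] <- uni_gibbs_chain(
      y, X, design$id_index - 1L, design$N, beta0, Bdiag,
      a_u, b_u, a_e, b_e,
      config$n_iter, config$burn_in, config$thin,
      beta_init, vy / 2, vy / 2,
      !is.null(fixed$sigma2_u), fixed$sigma2_u %||% 0,
      !is.null(fixed$sigma2_e), fixed$sigma2_e %||% 0)
    colnames(chains[[cc]]$beta) <- colnames(X)
    colnames(chains[[cc]]$u) <- design$individuals
  }

  beta_draws <- do.call(rbind, lapply(chains, `[[`, "beta"))
  u_draws <- do.call(rbind, lapply(chains, `[[`, "u"))
  s2u <- unlist(lapply(chains, `[[`, "sigma2_u"))
  s2e <- unlist(lapply(chains, `[[`, "sigma2_e"))

  summaries <- list(
    beta_mean = colMeans(beta_draws),
    beta_var = apply(beta_draws, 2L, var),
    sigma2_u_mean = mean(s2u),
    sigma2_e_mean = mean(s2e),
    # alternative reading: variances of the posterior distributions of the
    # effects themselves (averaged over individuals / pooled residuals)
    u_effect_var = mean(apply(u_draws, 2L, var)),
    e_effect_var = {
      fitted_mean <- X %*% colMeans(beta_draws)
      mean((y - fitted_mean - colMeans(u_draws)[design$id_index])^2) +
        mean(apply(u_draws, 2L, var))
    })

  structure(list(metabolite = metabolite, chains = chains,
                 beta_draws = beta_draws, u_draws = u_draws,
                 sigma2_u_draws = s2u, sigma2_e_draws = s2e,
                 summaries = summaries, config = config,
                 hyper = h, covariates = colnames(X),
                 individuals = design$individuals),
            class = "univariate_posterior")
}

#' Fit the independent (univariate-per-metabolite) model
#'
#' Maps [fit_univariate()] over all metabolites with per-metabolite derived
#' seeds. The result is the predecessor "independent" model: it is
#' consumable by the same predictive and flagging operations as the
#' multivariate fit, with the between-metabolite covariances implicitly
#' diagonal.
#'
#' @inheritParams fit_univariate
#' @return An `independent_fit`: a list of `univariate_posterior` objects
#'   (one per metabolite, in dataset order) plus shared metadata.
#' @export
fit_independent_model <- function(design, config = mcmc_config(),
                                  hyper = NULL) {
  stopifnot(inherits(design, "design_matrices"))
  fits <- vector("list", design$M)
  names(fits) <- design$metabolites
  for (m in seq_len(design$M)) {
    cfg_m <- config
    cfg_m$seed <- derive_seed(config$seed, 0L) + 1000L * m
    fits[[m]] <- tryCatch(
      fit_univariate(design, design$metabolites[m], cfg_m, hyper = hyper),
      error = function(e) stop(sprintf(
        "univariate fit failed for metabolite '%s': %s",
        design$metabolites[m], conditionMessage(e)), call. = FALSE))
  }
  structure(list(fits = fits, metabolites = design$metabolites,
                 individuals = design$individuals,
                 covariates = colnames(design$X), config = config),
            class = "independent_fit")
}

#' Summarise univariate fits into prior-building inputs
#'
#' Extracts, per metabolite, the posterior means and posterior variances of
#' the fixed-effect coefficients and the posterior means of both variance
#' components (plus the alternative effect-variance reading, switchable when
#' building the prior).
#'
#' @param fits An `independent_fit` or a list of `univariate_posterior`s.
#' @return A `prior_summaries` list with matrices `beta_mean`, `beta_var`
#'   ((L+1) × M) and vectors `sigma2_u`, `sigma2_e`, `u_effect_var`,
#'   `e_effect_var` (length M), ordered as the metabolites.
#' @export
summarize_for_prior <- function(fits) {
  if (inherits(fits, "independent_fit")) fits <- fits$fits
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "univariate_posterior")))
  covs <- lapply(fits, `[[`, "covariates")
  if (!all(vapply(covs, identical, TRUE, covs[[1L]])))
    stop("univariate fits have mismatched covariate structures",
         call. = FALSE)
  metabolites <- unname(vapply(fits, `[[`, "", "metabolite"))
  beta_mean <- vapply(fits, function(f) f$summaries$beta_mean,
                      numeric(length(covs[[1L]])))
  beta_var <- vapply(fits, function(f) f$summaries$beta_var,
                     numeric(length(covs[[1L]])))
  dim(beta_mean) <- dim(beta_var) <- c(length(covs[[1L]]), length(fits))
  dimnames(beta_mean) <- dimnames(beta_var) <- list(covs[[1L]], metabolites)
  structure(list(
    beta_mean = beta_mean, beta_var = beta_var,
    sigma2_u = setNames(vapply(fits, function(f) f$summaries$sigma2_u_mean, 0),
                        metabolites),
    sigma2_e = setNames(vapply(fits, function(f) f$summaries$sigma2_e_mean, 0),
                        metabolites),
    u_effect_var = setNames(vapply(fits, function(f) f$summaries$u_effect_var,
                                   0), metabolites),
    e_effect_var = setNames(vapply(fits, function(f) f$summaries$e_effect_var,
                                   0), metabolites),
    metabolites = metabolites, covariates = covs[[1L]]),
    class = "prior_summaries")
}
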