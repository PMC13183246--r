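#' Build the multivariate prior from univariate fits and observed signs
#'
#' Empirical-Bayes prior construction for the multivariate model. The
#' fixed-effect prior mean stacks the univariate posterior coefficient
#' means; the diagonal prior covariance `B` stacks their posterior
#' variances. The inverse-Wishart scale matrices take their diagonals from
#' the univariate posterior means of the random-intercept and residual
#' variances; every off-diagonal entry has magnitude 0.1 with its sign
#' taken from the pooled observed correlation matrix. The degrees of
#' freedom are 150\% of the number of metabolites (rounded up) by default.
#' If a scale matrix with off-diagonal magnitude 0.1 is not positive
#' definite, the magnitude is halved (0.1, 0.05, ...) until a Cholesky
#' factorisation succeeds, with a warning reporting the final magnitude.
#'
#' @param summaries A [summarize_for_prior()] result.
#' @param sign_matrix An M×M sign matrix, typically
#'   [observed_sign_matrix()].
#' @param nu_factor Degrees-of-freedom multiplier (default 1.5);
#'   `nu = ceiling(nu_factor * M)`.
#' @param off_diag Baseline off-diagonal magnitude of the scale matrices.
#' @param diag_source `"variance_means"` (default) uses the posterior means
#'   of the variance components for the scale-matrix diagonals;
#'   `"effect_variances"` uses the variances of the posterior distributions
#'   of the effects themselves.
#' @return A `prior_spec` with `beta0` ((L+1)×M), `B_diag` (length
#'   `(L+1)*M`, column-stacked order: metabolite 1's coefficients first),
#'   `Sigma2`, `SigmaEps2` (M×M) and `nu`.
#' @export
build_prior <- function(summaries, sign_matrix, nu_factor = 1.5,
                        off_diag = 0.1,
                        diag_source = c("variance_means",
                                        "effect_variances")) {
  stopifnot(inherits(summaries, "prior_summaries"))
  diag_source <- match.arg(diag_source)
  M <- length(summaries$metabolites)
  stopifnot(is.matrix(sign_matrix), all(dim(sign_matrix) == M),
            all(sign_matrix %in% c(-1, 1)))
  if (nu_factor <= 0) stop("nu_factor must be positive", call. = FALSE)

  if (diag_source == "variance_means") {
    d_u <- summaries$sigma2_u; d_e <- summaries$sigma2_e
  } else {
    d_u <- summaries$u_effect_var; d_e <- summaries$e_effect_var
  }
  if (any(d_u <= 0) || any(d_e <= 0) || any(summaries$beta_var <= 0))
    stop("non-positive prior diagonal entry; univariate summaries invalid",
         call. = FALSE)

  nu <- ceiling(nu_factor * M)
  if (nu <= M - 1)
    stop(sprintf("degrees of freedom %d <= M - 1 = %d: inverse-Wishart prior improper",
                 nu, M - 1L), call. = FALSE)

  scale_matrix <- function(diag_vals, label) {
    mag <- off_diag
    repeat {
      S <- sign_matrix * mag
      diag(S) <- diag_vals
      ok <- !inherits(try(chol(S), silent = TRUE), "try-error")
      if (ok) {
        if (mag < off_diag)
          warning(sprintf(
            "%s scale matrix not positive definite at off-diagonal magnitude %g; shrunk to %g",
            label, off_diag, mag), call. = FALSE)
        dimnames(S) <- list(summaries$metabolites, summaries$metabolites)
        return(list(S = S, mag = mag))
      }
      mag <- mag / 2
      if (mag < 1e-12) {
        S <- diag(diag_vals, M)
        dimnames(S) <- list(summaries$metabolites, summaries$metabolites)
        warning(sprintf("%s scale matrix off-diagonals dropped to 0", label),
                call. = FALSE)
        return(list(S = S, mag = 0))
      }
    }
  }
  s2 <- scale_matrix(unname(d_u), "random-effect")
  se2 <- scale_matrix(unname(d_e), "residual")

  structure(list(beta0 = summaries$beta_mean,
                 B_diag = as.vector(summaries$beta_var),
                 Sigma2 = s2$S, SigmaEps2 = se2$S, nu = as.numeric(nu),
                 off_diag_used = c(Sigma2 = s2$mag, SigmaEps2 = se2$mag),
                 metabolites = summaries$metabolites,
                 covariates = summaries$covariates),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> M = %d, nu = %g, off-diagonal magnitudes (%g, %g)\n",
              length(x$metabolites), x$nu, x$off_diag_used[1L],
              x$off_diag_used[2L]))
  invisible(x)
}

default_mv_inits <- function(design, prior) {
  M <- design$M
  beta_init <- qr.solve(design$X, design$Y)
  dim(beta_init) <- c(ncol(design$X), M)
  G0 <- prior$Sigma2 / max(prior$nu - M - 1, 1)
  R0 <- prior$SigmaEps2 / max(prior$nu - M - 1, 1)
  list(beta = beta_init, u = matrix(0, design$N, M), G = G0, R = R0)
}

#' Fit the multivariate model by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler for `Y = X beta + Z u + e` with
#' `u_i ~ N_M(0, G)`, `e_it ~ N_M(0, R)`, a normal prior on `vec(beta)`
#' and inverse-Wishart priors `G ~ IW(Sigma2, nu)`, `R ~ IW(SigmaEps2, nu)`
#' (parameterisation with prior mean `Sigma / (nu - M - 1)` for
#' `nu > M + 1`). The four conjugate full conditionals are cycled in the
#' order beta, u, G, R. `vec(beta)` is column-stacked: the coefficients of
#' metabolite 1 come first.
#'
#' Chains are initialised at the per-metabolite ordinary least-squares
#' coefficients with `u = 0` and both covariances at their prior means, and
#' each chain uses a seed derived deterministically from `config$seed`.
#'
#' @param design A [build_design()] result (complete rows only).
#' @param prior A [build_prior()] result (or hand-built `prior_spec`).
#' @param config An [mcmc_config()].
#' @param inits Optional list overriding initial values (`beta`, `u`, `G`,
#'   `R`).
#' @param fixed Optional list of blocks to clamp at their initial values
#'   (any of `beta`, `u`, `G`, `R` given as values); clamped blocks are
#'   never updated. Intended for conditional-correctness checks.
#' @return A `posterior_draws` object: per chain, arrays `beta`
#'   (S × (L+1) × M), `u` (S × N × M), `G` and `R` (S × M × M), plus
#'   metadata.
#' @export
gibbs_fit <- function(design, prior, config = mcmc_config(), inits = NULL,
                      fixed = list()) {
  stopifnot(inherits(design, "design_matrices"),
            inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  M <- design$M; P <- ncol(design$X)
  if (!identical(dim(prior$beta0), c(P, M)) ||
      length(prior$B_diag) != P * M || !all(dim(prior$Sigma2) == M))
    stop("prior and design dimensions disagree", call. = FALSE)

  ini <- default_mv_inits(design, prior)
  ini[names(inits)] <- inits
  for (nm in names(fixed)) ini[[nm]] <- fixed[[nm]]
  fix <- c(beta = "beta" %in% names(fixed), u = "u" %in% names(fixed),
           G = "G" %in% names(fixed), R = "R" %in% names(fixed))

  chains <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, cc))
    raw <- mv_gibbs_chain(
      design$Y, design$X, design$id_index - 1L, design$N,
      prior$beta0, prior$B_diag, prior$Sigma2, prior$SigmaEps2, prior$nu,
      config$n_iter, config$burn_in, config$thin,
      ini$beta, ini$u, ini$G, ini$R,
      fix[["beta"]], fix[["u"]], fix[["G"]], fix[["R"]])
    chains[[cc]] <- list(
      beta = aperm(raw$beta, c(3L, 1L, 2L)),
      u = aperm(raw$u, c(3L, 1L, 2L)),
      G = aperm(raw$G, c(3L, 1L, 2L)),
      R = aperm(raw$R, c(3L, 1L, 2L)))
    dimnames(chains[[cc]]$beta) <- list(NULL, colnames(design$X),
                                        design$metabolites)
    dimnames(chains[[cc]]$u) <- list(NULL, design$individuals,
                                     design$metabolites)
    dimnames(chains[[cc]]$G) <- dimnames(chains[[cc]]$R) <-
      list(NULL, design$metabolites, design$metabolites)
  }

  structure(list(chains = chains, config = config, prior = prior,
                 metabolites = design$metabolites,
                 individuals = design$individuals,
                 covariates = colnames(design$X)),
            class = "posterior_draws")
}

#' Pool retained draws across chains
#'
#' @param draws A `posterior_draws` object.
#' @return A list of arrays `beta`, `u`, `G`, `R` with all chains' retained
#'   draws stacked along the first dimension.
#' @export
pool_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  bind1 <- function(name) {
    arrs <- lapply(draws$chains, `[[`, name)
    d <- dim(arrs[[1L]])
    out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], 0L)),
                             d[2L], d[3L]))
    dimnames(out) <- c(list(NULL), dimnames(arrs[[1L]])[2:3])
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  list(beta = bind1("beta"), u = bind1("u"), G = bind1("G"), R = bind1("R"))
}

#' @export
print.posterior_draws <- function(x, ...) {
  S <- dim(x$chains[[1L]]$beta)[1L]
  cat(sprintf("<posterior_draws> %d chains x %d retained draws; M = %d, N = %d\n",
              length(x$chains), S, length(x$metabolites),
              length(x$individuals)))
  invisible(x)
}

gelman_rubin <- function(mat) {
  # mat: S x n_chains matrix of one scalar parameter
  S <- nrow(mat)
  W <- mean(apply(mat, 2L, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- S * var(colMeans(mat))
  sqrt(((S - 1) / S * W + B / S) / W)
}

#' Gelman-Rubin convergence diagnostics
#'
#' Computes the potential scale reduction factor (PSRF)
#' `sqrt(((S-1)/S * W + B/S) / W)` per scalar parameter — every
#' fixed-effect coefficient and every (upper-triangular, including
#' diagonal) entry of `G` and `R` — where `W` is the mean within-chain
#' variance and `B` the between-chain variance of the retained draws.
#'
#' @param draws A `posterior_draws` with at least two chains of at least 50
#'   retained draws each.
#' @param threshold Convergence is declared when the maximum PSRF does not
#'   exceed this value (default 1.1).
#' @return A `convergence_report`: data.frame `psrf` (parameter, value),
#'   `summary` (mean, sd, max) and logical `converged`. Parameters with
#'   zero within-chain variance get `NA` with a warning.
#' @export
psrf <- function(draws, threshold = 1.1) {
  stopifnot(inherits(draws, "posterior_draws"))
  n_chains <- length(draws$chains)
  if (n_chains < 2L)
    stop("PSRF requires at least 2 chains; rerun with a multi-chain mcmc_config",
         call. = FALSE)
  S <- dim(draws$chains[[1L]]$beta)[1L]
  if (S < 50L) stop("PSRF requires at least 50 retained draws per chain",
                    call. = FALSE)

  scalars <- list()
  bd <- dim(draws$chains[[1L]]$beta)
  covnames <- draws$covariates %||% paste0("b", seq_len(bd[2L]))
  for (p in seq_len(bd[2L])) for (m in seq_len(bd[3L]))
    scalars[[sprintf("beta[%s,%s]", covnames[p],
                     draws$metabolites[m])]] <-
      vapply(draws$chains, function(ch) ch$beta[, p, m], numeric(S))
  M <- length(draws$metabolites)
  for (nm in c("G", "R"))
    for (i in seq_len(M)) for (j in i:M)
      scalars[[sprintf("%s[%d,%d]", nm, i, j)]] <-
        vapply(draws$chains, function(ch) ch[[nm]][, i, j], numeric(S))

  vals <- vapply(scalars, gelman_rubin, 0)
  if (anyNA(vals))
    warning(sprintf("PSRF undefined for %d parameter(s) with zero within-chain variance",
                    sum(is.na(vals))), call. = FALSE)
  rep <- data.frame(parameter = names(vals), psrf = unname(vals),
                    stringsAsFactors = FALSE)
  structure(list(
    psrf = rep,
    summary = c(mean = mean(vals, na.rm = TRUE),
                sd = sd(vals, na.rm = TRUE),
                max = suppressWarnings(max(vals, na.rm = TRUE))),
    converged = isTRUE(suppressWarnings(max(vals, na.rm = TRUE)) <= threshold),
    threshold = threshold), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> mean PSRF %.4f (sd %.4f), max %.4f; %s (threshold %.2f)\n",
              x$summary["mean"], x$summary["sd"], x$summary["max"],
              if (x$converged) "converged" else "NOT converged", x$threshold))
  invisible(x)
}
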