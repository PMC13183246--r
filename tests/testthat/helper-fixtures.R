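# Shared fixtures and independent oracles for the test suite.

toy_table <- function() {
  # 2 individuals x 4 time points, 3 covariates, 2 metabolites
  data.frame(
    id = rep(c("A", "B"), each = 4L),
    timepoint = rep(1:4, 2L),
    age = rep(c(30, 45), each = 4L),
    bmi = rep(c(22.5, 27.0), each = 4L),
    sex = rep(c(0, 1), each = 4L),
    met1 = c(10.1, 10.4, 9.8, 10.0, 12.2, 12.0, 12.5, 12.1),
    met2 = c(5.0, 5.2, 4.9, 5.1, 6.3, 6.1, 6.4, 6.2),
    stringsAsFactors = FALSE)
}

toy_schema <- function() {
  metabo_schema("id", "timepoint", c("age", "bmi", "sex"), c("met1", "met2"))
}

toy_dataset <- function() metabo_dataset(toy_table(), toy_schema())

# Simulated dataset from the random-intercept generative model with known
# variance components; M metabolites, independent between metabolites.
make_mixed_data <- function(N, T, M = 1L, s2u = 4, s2e = 1, seed = 42L,
                            intercepts = rep(10, M)) {
  set.seed(seed)
  id <- rep(seq_len(N), each = T)
  age <- rnorm(N, 35, 12.6)[id]
  u <- matrix(rnorm(N * M, 0, sqrt(s2u)), N, M)
  Y <- matrix(rep(intercepts, each = N * T), N * T, M) + 0.02 * age +
    u[id, , drop = FALSE] + matrix(rnorm(N * T * M, 0, sqrt(s2e)), N * T, M)
  mets <- sprintf("met%d", seq_len(M))
  d <- data.frame(id = sprintf("i%03d", id), timepoint = rep(seq_len(T), N),
                  age = age, Y, stringsAsFactors = FALSE)
  names(d) <- c("id", "timepoint", "age", mets)
  metabo_dataset(d, metabo_schema("id", "timepoint", "age", mets))
}

# Monte-Carlo standard error of the mean of a (possibly autocorrelated)
# chain, by non-overlapping batch means.
batch_se <- function(x, n_batches = 40L) {
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(k) mean(x[((k - 1L) * b + 1L):(k * b)]), 0)
  sd(means) / sqrt(n_batches)
}

# Exhaustive shortest-window HPD search (independent of the package path).
brute_hpd <- function(x, level) {
  s <- sort(x)
  S <- length(s)
  w <- ceiling(level * S)
  best <- c(-Inf, Inf)
  for (i in seq_len(S - w + 1L)) {
    if ((s[i + w - 1L] - s[i]) < (best[2L] - best[1L]))
      best <- c(s[i], s[i + w - 1L])
  }
  best
}

# Fabricate a posterior_draws object whose chains are point masses at the
# supplied parameter values (S copies), for predictive/replicate plumbing
# tests with known truth.
fake_mv_draws <- function(design, beta, u, G, R, S = 200L, n_chains = 1L) {
  P <- ncol(design$X); M <- design$M; N <- design$N
  mk <- function(mat, d2, d3)
    array(rep(as.vector(mat), each = S), c(S, d2, d3))
  chains <- replicate(n_chains, list(
    beta = mk(beta, P, M), u = mk(u, N, M), G = mk(G, M, M),
    R = mk(R, M, M)), simplify = FALSE)
  structure(list(chains = chains,
                 config = mcmc_config(n_chains = max(n_chains, 1L),
                                      n_iter = S + 50L, burn_in = 0L,
                                      thin = 1L, seed = 1L),
                 prior = NULL, metabolites = design$metabolites,
                 individuals = design$individuals,
                 covariates = colnames(design$X)),
            class = "posterior_draws")
}

# Hand-built flag table; flags_spec is a data.frame with columns
# individual, timepoint, metabolite giving the TRUE cells.
fake_flag_table <- function(individuals, timepoints, metabolites, levels,
                            flagged_cells) {
  g <- expand.grid(individual = individuals, timepoint = timepoints,
                   metabolite = metabolites, level = levels,
                   stringsAsFactors = FALSE)
  key <- paste(g$individual, g$timepoint, g$metabolite)
  fkey <- paste(flagged_cells$individual, flagged_cells$timepoint,
                flagged_cells$metabolite)
  g$lower <- 0; g$upper <- 1
  g$observed <- 0.5
  g$flagged <- key %in% fkey
  class(g) <- c("flag_table", "data.frame")
  g
}

fake_summaries <- function(M, P = 2L, diag_u = 1, diag_e = 1) {
  mets <- sprintf("met%d", seq_len(M))
  covs <- c("(Intercept)", "age")[seq_len(P)]
  structure(list(
    beta_mean = matrix(0, P, M, dimnames = list(covs, mets)),
    beta_var = matrix(1, P, M, dimnames = list(covs, mets)),
    sigma2_u = setNames(rep_len(diag_u, M), mets),
    sigma2_e = setNames(rep_len(diag_e, M), mets),
    u_effect_var = setNames(rep_len(diag_u, M), mets),
    e_effect_var = setNames(rep_len(diag_e, M), mets),
    metabolites = mets, covariates = covs), class = "prior_summaries")
}

# One multivariate fit on a default scenario-1 dataset, shared by the
# calibration and recovery checks (computed lazily, once).
.fit_cache <- new.env(parent = emptyenv())
scenario1_fit <- function() {
  if (!is.null(.fit_cache$s1)) return(.fit_cache$s1)
  scen <- make_scenario(1)
  ds <- simulate_dataset(scen, 1L)
  design <- build_design(ds)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 2000L, burn_in = 800L,
                     thin = 2L, seed = 11L)
  ind_fit <- fit_independent_model(design, cfg)
  prior <- build_prior(summarize_for_prior(ind_fit),
                       observed_sign_matrix(ds))
  mv_fit <- gibbs_fit(design, prior, cfg)
  .fit_cache$s1 <- list(scen = scen, ds = ds, design = design,
                        ind_fit = ind_fit, prior = prior, mv_fit = mv_fit)
  .fit_cache$s1
}
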