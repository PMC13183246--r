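# metaboflag

Repeated measurements of a person's metabolite levels are remarkably
stable — so when an observed level falls outside the range the person's own
history predicts, that is biologically interesting. `metaboflag` fits a
**multivariate Bayesian generalised linear mixed model** to repeated
metabolite measurements (N individuals × T time points × M metabolites,
with covariates such as sex, age and BMI) and flags individuals whose
observed levels fall outside individual-level highest-posterior-density
(HPD) posterior-predictive intervals. It is aimed at metabolomics and
biomarker researchers studying intra-individual biological variation, for
whom per-analyte reference intervals ignore the strong dependence between
metabolites.

## Model

The responses are organised into an (N·T) × M matrix **Y** and modelled as

    Y = X β + Z u + ε,   u_i ~ N_M(0, G),   ε_it ~ N_M(0, R)

where **X** is the fixed-effect design (intercept plus L covariates), β is
the (L+1) × M coefficient matrix, **Z** the individual-indicator design,
u_i the M-variate random intercept of individual i, and the *dense*
covariance matrices **G** (between-individual) and **R** (residual) carry
the between-metabolite dependence that a one-metabolite-at-a-time model
discards. Priors are conjugate:

    vec(β) ~ N(vec(β₀), B),   G ~ IW(Σ², ν),   R ~ IW(Σε², ν)

with the hyperparameters built empirically: a univariate Bayesian
random-intercept model is fitted per metabolite, β₀ and the diagonal B
take the univariate posterior means and variances of the coefficients, the
scale-matrix diagonals take the univariate posterior means of the two
variance components, every off-diagonal has magnitude 0.1 signed by the
pooled observed correlation of **Y**, and ν = ⌈1.5 M⌉. The model is fitted
by a fully conjugate Gibbs sampler (compiled, multi-chain, seeded);
convergence is monitored with the Gelman–Rubin potential scale reduction
factor. For each individual, time point and metabolite, posterior
predictive draws β'x_it + u_i + N(0, R) yield shortest-window HPD
intervals at several widths (default 95 / 97.5 / 99%); an observation
outside its interval flags the individual for intra-individual variation
in that metabolite at that time point.

The package also contains the univariate predecessor (the "independent"
model), a three-scenario simulation study comparing the two by the mean
absolute difference (MAD) between correlation matrices of
posterior-predictive replicate datasets and the simulated data, and radar
plot / heatmap / boxplot reporting.

## Worked example

```r
library(metaboflag)

scenario <- make_scenario(1, list(N = 60))   # positive-dependence scenario
dataset  <- simulate_dataset(scenario, 1)
dataset
#> <metabo_dataset> 60 individuals, time points 1..4, 5 metabolites, 3 covariates, 240 rows, 0 missing metabolite cells

design <- build_design(dataset)
config <- mcmc_config(n_chains = 2, n_iter = 2000, burn_in = 800, thin = 2, seed = 1)
uni    <- fit_independent_model(design, config)       # univariate stage
prior  <- build_prior(summarize_for_prior(uni), observed_sign_matrix(dataset))
prior
#> <prior_spec> M = 5, nu = 8, off-diagonal magnitudes (0.1, 0.1)

fit <- gibbs_fit(design, prior, config)               # multivariate model
psrf(fit)
#> <convergence_report> mean PSRF 1.0024 (sd 0.0064), max 1.0320; converged (threshold 1.10)

pred  <- predictive_draws(fit, design, seed = 1)
flags <- flag_individuals(dataset, pred)              # 95 / 97.5 / 99% HPD
summarize_flags(flags, min_metabolites = 2)
#> <flag_summary> proportion of individuals with >= 2 metabolites flagged in a time point:
#>    95.0% HPD:   3.3% (2 of 60)
#>    97.5% HPD:   1.7% (1 of 60)
#>    99.0% HPD:   1.7% (1 of 60)
```

The convergence report says the two chains agree (PSRF ≈ 1 for every
fixed-effect, G and R entry). The flag summary counts an individual once
per HPD width if at least `min_metabolites` of their metabolites fall
outside their own predictive intervals at a single time point; the count
shrinks as the interval widens. `radar_plot()` draws one polar panel per
time point with the cohort in grey, the individual highlighted and
flagged metabolites starred; `pair_flag_counts()` + `pair_heatmap()` show
which metabolite pairs co-flag; `run_study()` + `mad_boxplot()` reproduce
the simulation comparison of the multivariate and independent models.

A command-line wrapper is installed at `inst/cli/metaboflag`
(`metaboflag fit|flag|simulate|report --config run.yaml`); every run
writes a manifest so results are exactly reproducible.

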