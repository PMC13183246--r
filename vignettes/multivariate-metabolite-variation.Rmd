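---
title: "Flagging intra-individual metabolite variation with a multivariate Bayesian mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging intra-individual metabolite variation with a multivariate Bayesian mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Metabolite concentrations measured repeatedly in the same person are
highly structured: levels differ persistently between individuals, vary
around each individual's own set-point over time, and co-vary strongly
across metabolites because metabolites share pathways. `metaboflag` models
all three layers at once. With $N$ individuals, $T$ time points, $M$
metabolites and $L$ covariates, the $(N\!\cdot\!T) \times M$ response
matrix $Y$ follows

$$Y = X\beta + Zu + \varepsilon,\qquad
  u_i \sim \mathcal{N}_M(0, G),\qquad
  \varepsilon_{it} \sim \mathcal{N}_M(0, R),$$

where $X$ holds an intercept column and the covariates, $\beta$ is
$(L{+}1)\times M$, $Z$ indicates which individual each row belongs to, and
the random intercept $u_i$ shifts all of individual $i$'s measurements.
The point of the model is that $G$ and $R$ are *dense*: their
off-diagonals carry between-metabolite dependence at the individual and
residual level respectively. The predecessor "independent" model — also
provided, as `fit_independent_model()` — is the special case of diagonal
$G$ and $R$, fitted one metabolite at a time.

Assumptions worth keeping in mind: responses are Gaussian on the supplied
scale (the package deliberately applies no transformation — if your
metabolites are right-skewed, log-transform before modelling); random
intercepts are exchangeable across individuals; covariate effects are
linear and common to all individuals; and rows with any missing metabolite
value are excluded from the likelihood (complete-case per row), which
keeps all full conditionals exact. Per-cell imputation is out of scope.

## Empirical-Bayes prior construction

All priors are conjugate:
$\mathrm{vec}(\beta) \sim \mathcal{N}(\mathrm{vec}(\beta_0), B)$ with $B$
diagonal, and $G \sim \mathcal{IW}(\Sigma^2, \nu)$,
$R \sim \mathcal{IW}(\Sigma_\varepsilon^2, \nu)$ in the parameterisation
with prior mean $\Sigma/(\nu - M - 1)$ for $\nu > M + 1$. `build_prior()`
assembles the hyperparameters from a univariate Bayesian random-intercept
fit per metabolite:

* $\beta_0$ stacks the univariate posterior means of the coefficients and
  the diagonal of $B$ their posterior variances;
* the diagonals of $\Sigma^2$ and $\Sigma_\varepsilon^2$ are the
  univariate posterior means of the random-intercept and residual
  variances. The phrase "variance of the posterior of the effects" admits
  a second reading — the posterior variance of the effects themselves —
  which is also computed and selectable via
  `diag_source = "effect_variances"`; the posterior-mean reading is the
  default because scale-matrix diagonals must live on the variance scale
  of the data;
* every off-diagonal entry has magnitude 0.1, signed by the *pooled*
  Pearson correlation matrix of the observed $Y$ (a single matrix is
  needed, so the pooled estimate rather than any per-timepoint one is the
  natural choice). An exactly zero correlation maps to $+1$ — a documented
  tie-break, immaterial in practice since pooled sample correlations are
  almost never exactly zero;
* $\nu = \lceil 1.5\,M\rceil$, one value shared by both priors.

With small variance diagonals the fixed $\pm 0.1$ off-diagonals can make a
scale matrix indefinite. `build_prior()` then halves the off-diagonal
magnitude ($0.1 \to 0.05 \to \dots$) until a Cholesky factorisation
succeeds and warns loudly with the final magnitude. This repair preserves
the signs and the diagonal and is the smallest change that restores
validity.

The univariate stage itself uses weakly informative, scale-aware priors:
each coefficient $\mathcal{N}(0, 10^8 \cdot \widehat{\mathrm{var}}(y))$
and both variance components inverse-gamma with shape $0.001$ and rate
$0.001 \cdot \widehat{\mathrm{var}}(y)$. This stage only harvests
posterior summaries, so its priors are chosen to have negligible
influence; all of them are overridable through the `hyper` argument.

## Gibbs sampling

The Gaussian model with these priors is fully conjugate, so
`gibbs_fit()` cycles exact full conditionals (a systematic scan:
$\beta$, $u$, $G$, $R$):

1. $\mathrm{vec}(\beta)$: multivariate normal with precision
   $B^{-1} + R^{-1} \otimes X^\top X$. The vec convention is
   column-stacking — metabolite 1's $(L{+}1)$ coefficients first — and is
   used consistently in the prior, the sampler and the tests.
2. $u_i$: $M$-variate normal with precision $G^{-1} + T_i R^{-1}$, where
   $T_i$ is the number of modelled rows of individual $i$.
3. $G$: inverse-Wishart with scale $\Sigma^2 + \sum_i u_i u_i^\top$ and
   $\nu + N$ degrees of freedom.
4. $R$: inverse-Wishart with scale
   $\Sigma_\varepsilon^2 + \sum_{it} e_{it} e_{it}^\top$ and $\nu + n$
   degrees of freedom ($n$ = modelled rows).

The chains are written in C++ (RcppArmadillo) but draw every random number
through R's RNG, so a single `set.seed()` determines everything. Chain $c$
of a run with master seed $s$ uses seed $(s + 104729\,c) \bmod (2^{31}-1)$;
per-metabolite univariate fits offset the master seed by $1000 m$ first.
Initialisation is deterministic: $\beta$ at ordinary least squares, $u$ at
zero, covariances at their prior means — so reruns are bitwise identical.
Inverse-Wishart draws use the Bartlett decomposition; a Cholesky failure
anywhere aborts with the iteration and block named rather than continuing
silently.

Defaults follow the reference protocol: 4 chains × 5000 iterations, 2000
burn-in, thinning 3 (1000 retained draws per chain). Convergence is
assessed with the Gelman–Rubin potential scale reduction factor,
$\sqrt{((S-1)/S\,W + B/S)/W}$, computed for every $\beta$, $G$ and $R$
entry, with the conventional 1.1 threshold. Two identical chains give the
closed-form floor $\sqrt{(S-1)/S}$; chains with zero within-chain variance
yield `NA` with a warning rather than a spurious value.

Correctness of the sampler is established by the test suite rather than by
trust: the $\beta$ conditional is checked against the closed-form
generalised-least-squares posterior with $(G, R)$ clamped (the `fixed`
argument exists precisely to turn conditionals into testable exact draws),
the $G$ conditional against the analytic inverse-Wishart mean, the whole
sampler by a successive-conditional ("getting it right") simulation whose
stationary distribution must be the prior, and the $M = 1$ case against
the independent univariate sampler by Kolmogorov–Smirnov tests under
matched priors.

## Predictive intervals and flagging

For each retained draw $s$ and each (individual, time point) cell,
`predictive_draws()` simulates
$\tilde{y}_{it}^{(s)} = \beta^{(s)\top} x_{it} + u_i^{(s)} + \eta^{(s)}$,
$\eta^{(s)} \sim \mathcal{N}_M(0, R^{(s)})$. Cells are available for every
observed pair, including rows excluded from the likelihood for missing
metabolite values (their covariates are known); new, unseen individuals
are refused — there is no $u_i$ posterior for them.

`hpd_interval()` is the shortest-window estimator: among all windows of
$\lceil \mathrm{level} \cdot S\rceil$ consecutive order statistics, the
narrowest wins, ties going to the lower start index. It is checked against
an exhaustive brute-force search and against normal-theory quantiles. An
equal-tail alternative is available (`interval = "equal_tail"`). Empirical
HPD windows are not mathematically guaranteed to nest across levels;
`flag_individuals()` counts and reports observed nesting violations
instead of hiding them, and the suite asserts that flag *counts* are
non-increasing as the interval widens.

Flags are marginal per metabolite (an individual is flagged for metabolite
$m$ at time $t$), matching how practitioners read the results; joint
Mahalanobis-style outlier scores are out of scope. Summaries follow the
"in a single time point" rule: an individual counts at threshold $k$ only
if some one time point has $\ge k$ flagged metabolites — flags spread
across time points do not accumulate.

One consequence of the in-sample protocol deserves emphasis. The observed
point is part of the training data when its own interval is computed, so
the predictive distribution is partially conditioned on the very value
being tested and the outside-rate at a 95% interval sits *below* 5%. With
known $(G, R)$ the discrepancy $d_{it} = y_{it} - E[y_{it} \mid \text{posterior}]$
has covariance
$(I - T W) G (I - T W)^\top + (I - W) R (I - W)^\top + (T-1) W R W^\top$
with $W = (G^{-1} + T R^{-1})^{-1} R^{-1}$, against a predictive variance
of $\mathrm{diag}(R + (G^{-1} + T R^{-1})^{-1})$; the implied outside-rate
is well under the nominal 5% whenever the between-individual variance is
appreciable. The test suite computes this closed form and verifies the
fitted model reproduces it. Leave-one-out prediction would restore nominal
calibration but is deliberately out of scope: the in-sample protocol is
the predecessor method's, and the flags are meant as a screening rank, not
a calibrated test.

## The simulation study and its generator

`make_scenario()` fixes three dependence regimes for $M = 5$ metabolites,
$N = 150$ individuals, $T = 4$ time points and $L = 3$ covariates:

* **Scenario 1** (positive dependence): correlation targets
  $(0.9, 0.7, 0.55, 0.3, 0.65, 0.5, 0.25, 0.45, 0.15, 0.1)$ for the pairs
  in row-major upper-triangle order — all in $[0.1, 0.9]$, five of ten in
  $[0.5, 0.9]$.
* **Scenario 2** (independence): all off-diagonals exactly zero.
* **Scenario 3** (mixed dependence): targets
  $(0.6, -0.5, 0.25, -0.2, -0.35, 0.15, -0.1, 0.2, 0.05, -0.25)$ — all in
  $[-0.6, 0.6]$, seven of ten in $[-0.3, 0.3]$.

Both fixed target lists were verified positive definite before use; if a
user override produces an indefinite matrix it is projected to the nearest
positive definite correlation matrix (eigenvalue clipping plus
re-normalisation) and the scenario's range constraints are re-checked —
an override that cannot satisfy them is an error, not a silent adjustment.
Targets convert to covariances with per-metabolite variances of 4
(random effects) and 1 (residuals), i.e. an intra-class correlation of
0.8, consistent with the high temporal stability reported for fasting
plasma metabolites; the same correlation structure is used for $G$ and
$R$. Intercepts are $10, 11, \dots, 14$ with small covariate effects
(age 0.02, BMI 0.05, sex 0.5), and covariates are drawn once per
individual from the cohort summary laws age $\sim \mathcal{N}(35, 12.6^2)$,
BMI $\sim \mathcal{N}(24.1, 3.07^2)$, sex $\sim$ Bernoulli$(111/164)$.

What the generator emulates: realistic dimensions, covariate
distributions, persistent individual set-points and dense metabolite
dependence. What it does not: missing values, non-Gaussian or zero-inflated
concentrations, drift over time, batch effects, or covariates that change
within an individual. A clean pass on these simulations therefore shows
the machinery is correct under the model's own assumptions — not that the
model fits any particular cohort.

`run_study()` fits both models to each simulated dataset (the multivariate
path includes its univariate prior stage), draws posterior-predictive
replicate datasets from systematically spaced retained draws (spaced, not
random, so replicate selection is reproducible), and scores each replicate
by the mean absolute difference (MAD) between its per-timepoint
correlation matrix and the simulated data's — the mean of
$|A - B|$ over the strict upper triangle, excluding the identically-zero
diagonal; undefined correlations (a metabolite constant at a time point)
drop out pairwise with the denominator adjusted. A failed fit skips that
dataset with a warning; more than 20% skipped aborts the study. The
expected pattern, asserted by the suite, is that the multivariate model's
median MAD beats the independent model's at every time point under
positive dependence, matches it (within 0.05) under independence, and is
never meaningfully worse under mixed dependence.

## Problem sizes and runtime choices

The shipped tests and the acceptance script scale the study down — 5
datasets per scenario at $N = 80$ with 2 chains × 1500 iterations and 100
replicates, and single scenario-1 fits at $N = 150$ with 2 chains × 2000
iterations — sizes chosen so the whole suite completes in about a minute
on one core while every Monte-Carlo comparison retains its power; the
compiled sampler makes the full default protocol (4 × 5000) a matter of
seconds for these dimensions as well. Successive-conditional and
conditional-correctness checks use deliberately tiny instances
($M = 2$, $N \le 10$) where their closed-form oracles are cheap and exact.
The "getting it right" check uses $\nu = 8$ rather than the recipe's
$\lceil 1.5 M\rceil = 3$, because at $M = 2$ the inverse-Wishart mean (the
moment being compared) only exists for $\nu > M + 1$.

## Limitations

Runtime grows with $M^2$ in the covariance updates and linearly in chains,
iterations and individuals; at hundreds of metabolites both fitting and
the radar/heatmap displays stop being practical, and sparser or
approximate inference would be the way forward. The Gaussian response is
an assumption, not a fact about concentrations — truncated, skew-$t$ or
zero-inflated extensions would change the conditionals and are not
provided. Flags at different levels, metabolites and time points are
correlated, so the summaries are descriptive screening output; no
multiplicity correction is applied or implied.
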