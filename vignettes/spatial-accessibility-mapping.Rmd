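---
title: "Spatial accessibility to thrombectomy and Bayesian mapping of stroke mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial accessibility to thrombectomy and Bayesian mapping of stroke mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeaccess)
```

## The problem

Mechanical thrombectomy (MT) is an endovascular treatment for acute
ischemic stroke whose benefit decays rapidly with time to treatment.
Whether a population can actually reach an MT-capable hospital therefore
varies in space, and that variation may translate into small-area
differences in stroke mortality. `strokeaccess` implements an ecological
analysis of this question at the municipality level: quantify spatial
accessibility to MT, standardize mortality for age and sex, and relate
accessibility to mortality risk with models that respect the spatial
dependence of areal data.

The package is exercised end to end on synthetic landscapes with known
ground truth. Every analysis stage is a tested exported function, and the
death counts are simulated from the same generative model the Bayesian
stage fits, so parameter recovery, convergence and model selection are
directly checkable.

## Accessibility: two-step floating catchment area

Demand lives on a fine mesh: $D_i$ is the population aged 65 and over in
mesh $i$. Supply lives at hospitals: $S_j$ neurointerventionalists at site
$j$. With travel times $d_{ij}$ in minutes, the decay weight is

$$f(d) = \begin{cases} e^{-\beta d} & d < d_0 \\ 0 & d \ge d_0,\end{cases}$$

with friction $\beta = 0.07$ per minute and catchment $d_0 = 120$ minutes
by default. The catchment boundary is excluded (a 120-minute trip gets
weight zero), reading the case split literally. Step 1 computes each
hospital's demand-to-supply ratio
$r_j = S_j / \sum_{d_{ij} < d_0} D_i f(d_{ij})$; step 2 sums reachable
ratios into a mesh-level index $A_i = \sum_{d_{ik} < d_0} r_k f(d_{ik})$.
Two municipal aggregates follow: PWSAI, the demand-weighted mean of $A_i$
(providers per capita), and PWTT, the demand-weighted mean travel time to
the *nearest* hospital, reported in hours. Nearest is defined by travel
time, not distance, because the whole analysis is framed in travel time.

When every hospital's catchment contains positive weighted demand, total
supply is conserved: $\sum_i D_i A_i = \sum_j S_j$. This algebraic
identity is the main correctness check on the implementation and holds to
$10^{-9}$ relative error on random landscapes. A hospital whose catchment
holds no weighted demand has an undefined ratio; it is dropped with a
warning rather than aborting the run, the same pragmatic treatment an
isolated island facility receives in real applications.

## Standardization and SMR

Expected deaths use indirect standardization over 2 sexes × 17 five-year
age bands (0–4 through 75–79, then 80+):
$E_i = \sum_{s,a} n_{i,s,a}\, m_{s,a}$ with national reference rates
$m_{s,a}$. The standardized mortality ratio is $O_i / E_i$ (crude) or the
posterior of the model relative risk $\theta_i$ (model-based). In
self-contained synthetic runs the reference rates come from the rate
generator itself — municipality-level simulated deaths carry no stratum
detail from which national rates could be re-derived, so the generator's
rates play the role of the national schedule. Counts are integers
throughout; when a multi-year observation period is emulated, the summed
count is the likelihood response and any per-year average is a reporting
convention only.

## The non-spatial screen

A negative-binomial GLM (NB2, variance $\mu + \mu^2/r$) with offset
$\log E_i$ screens the covariates: variance inflation factors are computed
from auxiliary least-squares regressions on the standardized design, and
covariates are removed iteratively (largest VIF first, ties by column
order) while any VIF exceeds 5. The synthetic covariates include three
compositional industry shares summing to 100 up to rounding noise;
this near-exact collinearity reliably pushes one share's VIF far above the
threshold, which is the behaviour the screen exists to catch. Residual
spatial autocorrelation is then tested with Moran's I. The statistic uses
the binary queen adjacency as-is; inference is a two-sided permutation
test (999 permutations, seeded) rather than the normal approximation,
which is more robust at the few hundred areas typical here, and the
analytic null expectation $-1/(n-1)$ is reported alongside. Pearson
residuals $(O-\hat\mu)/\sqrt{\hat\mu + \hat\mu^2/\hat r}$ are used so the
values are variance-comparable across areas.

## The spatial model

The disease-mapping stage is a Poisson log-linear model with a Leroux
conditional-autoregressive random effect:

$$O_i \sim \text{Poisson}(E_i \theta_i), \qquad
\log \theta_i = \alpha + X_i \beta + \psi_i,$$

$$\psi \sim N\!\left(0,\; \tau^2\, Q(\rho)^{-1}\right), \qquad
Q(\rho) = \rho\,(D_w - W) + (1-\rho)\, I,$$

with binary queen adjacency $W$, $\tau^2 \sim$ Inverse-Gamma(1, 0.01)
(density $\propto x^{-\text{shape}-1} e^{-\text{scale}/x}$) and
$\rho \sim U(0,1)$. The model interpolates between independent
log-normal heterogeneity ($\rho = 0$) and the intrinsic autoregression
($\rho = 1$, improper because every graph Laplacian has a zero
eigenvalue).

### Sampler

The Poisson likelihood admits no conjugate update for $\alpha$, $\beta$ or
$\psi$, so the sampler is Metropolis-within-Gibbs (implemented in C++):

* $\alpha$ and each $\beta_k$: adaptive random-walk Metropolis under
  diffuse $N(0, 10^5)$ priors, steps tuned toward 30–50% acceptance during
  burn-in and frozen afterwards to preserve detailed balance;
* $\psi_i$: single-site random walks against the product of the Poisson
  likelihood and the Leroux full conditional, whose mean is
  $\rho \sum_l w_{il}\psi_l / (\rho w_{i+} + 1 - \rho)$ and variance
  $\tau^2/(\rho w_{i+} + 1 - \rho)$;
* $\tau^2$: conjugate Gibbs draw from
  Inverse-Gamma(shape $+\,n/2$, scale $+\,\psi^\top Q(\rho)\psi / 2$);
* $\rho$: random walk on the logit scale with the Jacobian correction,
  using $\log\det Q(\rho) = \sum_m \log(\rho\lambda_m + 1 - \rho)$ from
  the Laplacian eigenvalues $\lambda_m$, computed once per graph, which
  makes each proposal $O(n)$.

$\alpha$ and the mean of $\psi$ are confounded, so $\psi$ is recentred to
sum zero every iteration with the mean absorbed into $\alpha$; the linear
predictor — hence the likelihood — is unchanged by this move. Chains are
seeded `seed`, `seed + 1`, ... and are bit-reproducible. The default
schedule is 3 chains × 520,000 iterations with 20,000 burn-in and
thinning every 100 (read as keep-every-100th), retaining 5,000 draws per
chain, 15,000 in total; the retention arithmetic is exposed as
`mcmc_retention()` so it can be checked without sampling.

### Outputs and diagnostics

Coefficients are reported as relative risks per standard deviation
(covariates are standardized before fitting; the per-column SDs are kept
for back-transformation). Posterior medians and 95% credible intervals
come from pooled draws. Convergence is the classical non-split
Gelman–Rubin factor per parameter with 1.1 as an advisory threshold.
Model comparison uses WAIC computed from the pointwise log-likelihood
matrix, reported both pooled and per chain (chain-1 WAIC is a first-class
output of the comparison table). Fitted SMRs are posterior medians and
intervals of $\theta_i$, and the residual Moran's I is computed on
Pearson-scale residuals of the posterior-median fit.

An inverse-gamma prior sensitivity variant (0.5, 0.005) is supported via
`car_config()`; on a well-identified 400-area instance the relative-risk
medians move by less than 0.01 between the two priors (this is a tested
property, not an assumption). The published sensitivity pairing lists the
main prior twice, which is likely typographical; the package simply makes
the prior a configuration parameter rather than guessing the intended
third value.

## Synthetic landscapes

`gen_landscape()` builds a square mesh grid partitioned into square-block
municipalities — blocks make queen adjacency unambiguous in the absence of
real polygons. Mesh demand populations are log-normal (default log-mean
$\log 50$, log-sd 1) and rounded; the distribution is an assumption chosen
for right-skewed positive counts, not an inference about any real mesh
system. Default geometry (20 × 20 meshes at 6 km spacing, 40 km/h) spans
straight-line drive times from minutes to beyond the 120-minute catchment,
so both well-served and under-served municipalities occur. Hospitals sit
at distinct random meshes with $1 + \text{Poisson}(2)$ specialists.
Population tables preserve each municipality's 65+ demand exactly through
a multinomial split over the elderly sex × age cells; reference rates rise
exponentially with age with a male excess and are forced nondecreasing.
Covariates emulate the regression design: Dirichlet(2, 5, 13) industry
shares scaled to 100 with uniform(±0.5) rounding noise, log-normal
medical-resource rates and an education share.

`simulate_deaths()` draws $\psi$ exactly by Cholesky factorization of the
Leroux precision (exact and cheap at these sizes) and then Poisson
counts — the same generative process the CAR stage fits, which is what
makes recovery testable. What the generator does **not** emulate: road
networks (travel times are Euclidean at constant speed), coastline or
island geometry, the real ~1,800-unit municipal structure, or any
systematic correlation between accessibility and the socioeconomic
covariates. Passing tests therefore demonstrate the correctness and
calibration of the *methods* under the stated generative assumptions, not
substantive conclusions about any real health system.

## Verification scales

Desk-scale checks use sizes chosen to make Monte-Carlo noise small
relative to the tested margins: parameter recovery and WAIC model
selection run on 400-area lattices with a reduced schedule (3 chains ×
20,000 iterations, 5,000 burn-in, thin 10) over 20 seeded replicates;
the GMRF sampling distribution is checked against the analytic covariance
on a 16-area lattice with 20,000 draws; conservation is checked on 50
random landscapes. The full 520,000-iteration schedule is validated
through its retention arithmetic rather than by running it.

## Pipeline

`run_pipeline()` orchestrates simulate → access → expected → screen →
fit → report from one YAML configuration (versioned schema, unknown keys
rejected), writing each stage's tables as CSV plus a JSON manifest of
seeds and file hashes. One global seed deterministically spawns per-stage
seeds, so runs are reproducible end to end; stages whose outputs already
exist are skipped, and the report stage is a pure function of the fitted
model table, so deleting only `report.csv` re-reports without
re-sampling. The package's interface is these functions — it is an
analysis library, not a shell tool, so the pipeline's subcommands are R
calls rather than a command-line binary.

## Known limitations

* Travel times are straight-line; network detours, congestion and modal
  differences are out of scope.
* The Moran's I permutation test and the residual definitions are explicit
  choices; published analyses rarely state theirs, so numeric agreement
  with any particular published residual statistic is not claimed.
* Single-site updates mix slowly when $\rho$ is near 1 and areas are many;
  the adaptive steps mitigate but do not remove this.
* The intrinsic limit $\rho = 1$ is rejected rather than handled by a
  constrained parametrization.
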