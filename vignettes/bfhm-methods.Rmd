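---
title: "Joint bi-factor modeling of response accuracy and response time: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint bi-factor modeling of response accuracy and response time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Computer-based tests record not only whether an examinee answers an item
correctly (response accuracy, RA) but also how long the answer takes
(response time, RT). In a *between-item multidimensional* test, items come
in groups that each measure one specific latent trait — think of subtests
probing distinct abilities — while a general trait plausibly runs through
every item. A unidimensional joint model misrepresents such data; a purely
multidimensional one ignores the shared general component on both the
ability and the speed side. `bfhm` implements a bi-factor *joint
hierarchical* model in which both the accuracy side and the time side have
a general factor plus orthogonal specific factors, and the two sides are
linked through correlated person and item parameters.

## Level 1: measurement models

For person $i$ and item $j$ assigned to specific dimension $s(j)$, accuracy
follows a bi-factor two-parameter logistic IRT model

$$P(u_{ij}=1) = \frac{1}{1+\exp\{-(d_j + a_{gj}\,\theta_{gi} +
a_{sj}\,\theta_{s(j)i})\}},$$

with general discrimination $a_{gj} > 0$, specific discrimination
$a_{sj} > 0$ and location $d_j$. Log response time follows a bi-factor
lognormal model

$$\ln T_{ij} = \beta_j - (\alpha_{gj}\,\tau_{gi} +
\alpha_{sj}\,\tau_{s(j)i}) + \xi_{ij}, \qquad
\xi_{ij} \sim N(0, \sigma_j^2),$$

where $\beta_j$ is the item's time intensity (expected log-seconds),
$\alpha_{gj}, \alpha_{sj} > 0$ are speed slopes and $1/\sigma_j$ acts as a
time discrimination. Each item loads on exactly one specific dimension
(the between-item constraint, enforced by `loading_pattern()`);
within-item multidimensionality is rejected at validation.

The RT likelihood is defined as a normal density **on log time**, not as
the Jacobian-adjusted lognormal density on the seconds scale. This is a
deliberate choice: all model variants share the transform, so relative
model comparisons are unaffected, while absolute fit indices are on the
log-time scale and should not be compared against indices computed on the
seconds scale.

## Level 2: population structure

Person factors pair ability with speed. The general pair
$(\theta_g, \tau_g)$ and each specific pair $(\theta_s, \tau_s)$ are
bivariate standard normal with free correlations; all cross-factor
covariances are fixed at zero (bi-factor orthogonality). The item pair
$(d_j, \beta_j)$ is bivariate normal with free moments
$(\mu_d, \mu_\beta, \sigma_d, \sigma_\beta, \rho_{d\beta})$. A negative
$\rho_{d\beta}$ means harder items demand more time.

Identification fixes all person-factor means at 0 and variances at 1 (so
person covariances *are* correlations), and constrains every
discrimination and slope positive, which pins the orientation of each
factor in every draw — factor reflection is impossible by construction,
and the test suite asserts positivity on every retained draw.

One design question the bi-factor literature leaves open is whether the
ability–speed correlation is shared across specific dimensions. We expose
a *separate* correlation per dimension: the specific traits are distinct
constructs and their coupling with speed need not be equal.

### Nested variants

The model family collapses by constraints, all exposed through
`model_spec()`:

* **BFHM** — general + specific factors on both sides;
* **CMHM** — no general factors ($a_g \equiv \alpha_g \equiv 0$);
* **PMHM** — CMHM with a single latent speed on the RT side;
* **UNIDIM** — one ability, one speed (the classical hierarchical model).

These are exact likelihood restrictions; the unit tests verify bit-level
equality of the pointwise likelihood along the chain BFHM → CMHM → PMHM →
UNIDIM under the corresponding constraints.

For the PMHM the literature does not spell out how the single speed
relates to the $K$ specific abilities. We model it as a factor regression
$\tau = \sum_k \rho_k \theta_{sk} + \sqrt{1-\sum_k\rho_k^2}\,\varepsilon$,
which leaves the abilities mutually orthogonal, gives
$\mathrm{Cor}(\tau, \theta_{sk}) = \rho_k$ exactly, keeps
$\mathrm{Var}(\tau) = 1$, and reduces to the classical single correlation
when $K = 1$ — so UNIDIM is literally PMHM at $K=1$. The prior on
$(\rho_1,\dots,\rho_K)$ is uniform over the unit ball, the direct
generalization of the uniform (LKJ with shape 1) prior used for the 2x2
blocks.

## Priors

* $a_{gj}, a_{sj}, \alpha_{gj}, \alpha_{sj}, 1/\sigma_j \sim N(0,1)$
  truncated to $(0,\infty)$. The prior (and the sampler parameterization)
  sit on the time *discrimination* $1/\sigma_j$; $\sigma_j$ is derived.
* 2x2 correlation blocks: LKJ($\eta$), $\eta = 1$ by default, i.e. a
  uniform correlation.
* $\mu_d \sim N(0, 0.5)$, $\mu_\beta \sim N(4, 0.5)$ — the second argument
  is a standard deviation — and $\sigma_d, \sigma_\beta \sim N(0,1)$
  truncated positive. The $(d,\beta)$ covariance uses the
  scale–correlation decomposition with the LKJ prior on the correlation.

All defaults live in `prior_config()` and are weakly informative at the
scale of typical test data (log-seconds around 3–5, discriminations below
about 2.5).

## Estimation

`fit_bfhm()` runs the package's own No-U-Turn sampler (NUTS), a
Hamiltonian Monte Carlo variant that adapts its trajectory length, written
in C++ against the model family's analytic gradients. Relevant
implementation choices:

* **Unconstrained parameterization.** Positive parameters are sampled on
  the log scale, correlations via `atanh` (with $q =
  \operatorname{sech}(y)$ computed directly so that $\rho \to \pm 1$ stays
  numerically stable), and the PMHM correlation vector through a smooth
  bijection onto the unit ball whose Jacobian makes the prior uniform.
* **Non-centered hierarchies.** Both $(d_j, \beta_j)$ and every person
  speed are expressed as standardized residuals scaled inside the model,
  which removes the funnel geometry that plagues centered hierarchical
  samplers.
* **Adaptation.** Dual-averaging tunes the step size to a target
  acceptance statistic of 0.8; a diagonal mass matrix is estimated once
  from the middle of warmup (Welford accumulation, regularized toward
  unity) after which step-size adaptation restarts.
* **Stability.** Bernoulli log-likelihoods use the `log1p(exp(.))` form
  with a single exponential per cell, stable for linear predictors up to
  the stated range of roughly 700 in magnitude. Iterations whose energy
  error exceeds 1000 are flagged divergent.
* **Initialization** is random but moderate (loadings in (0.2, 1.5),
  traits within two standard deviations), seed-controlled per chain, which
  avoids stalls at the truncation boundary.

The default protocol (`sampler_config()`) mirrors the estimation routine
this model family is customarily run with: 2 chains of 40,000 iterations,
the first half warmup, thinning of 2, giving 10,000 retained draws per
chain; convergence is declared when every split-chain PSRF is below 1.1.
The iteration count in that protocol is sized for generic MCMC; NUTS
reaches the same Monte-Carlo error with far fewer iterations, and the
package's own studies use 400–600 iterations per chain. We interpret "40,000
iterations with the final half retained" as per-chain counts with
pre-thinning totals; the interpretation is recorded in `fit_meta.json` and
every element is configurable.

The split-chain PSRF halves each chain before computing the
between/within variance ratio, so within-chain drift is detected even
when chains agree in distribution; constant chains return 1 by convention
with a warning.

Two independent checks validate the engine: prior-only sampling
reproduces the prior moments, and on the unidimensional model the NUTS
posterior means agree with an independently coded Gibbs sampler (JAGS)
within Monte-Carlo error.

## Model comparison

WAIC and PSIS-LOO are computed from pointwise log-likelihood draws on the
deviance ($-2\cdot$) scale. The pointwise unit is the **person × item
cell**, separately for the RA and the RT component: the two cells are
conditionally independent given the latent traits, and only cell-level
pointwise likelihoods support reporting RA, RT and total columns that add
up exactly (`fit_indices()` asserts the additivity). The PSIS
implementation follows the published Pareto-smoothed importance sampling
algorithm (empirical-Bayes generalized-Pareto tail fit with the standard
weak-prior regularization) and matches the `arviz` reference
implementation to machine-level agreement in the test suite; tail-shape
estimates above 0.7 trigger a warning.

Because the pointwise unit is a convention, absolute WAIC/LOO values are
comparable only across models fitted by this package on the same cells;
the acceptance surface for model selection is the *ordering* of the
variants.

## The simulator

`simulate_dataset()` generates data under the model itself:

* loadings and the time discrimination $1/\sigma_j$ from the standard
  normal truncated to $(0,\infty)$ (equivalently half-normal, drawn as
  $|N(0,1)|$, which is exact);
* $(d_j, \beta_j)$ bivariate normal with means $(0, 4)$, variances
  $(1, 0.25)$ and covariance $-0.25$;
* one ability–speed correlation per factor from $U(-1,1)$ (optionally
  fixed), then standard bivariate normal pairs;
* $u_{ij} = 1$ when the model probability is greater than or equal to an
  independent uniform draw (the tie has probability zero; the rule is
  fixed for reproducibility), and $\ln T_{ij}$ normal with SD $\sigma_j$.

Item draws, person draws, response noise and time noise consume separate
substreams derived from one master seed, so changing $N$ leaves the item
parameters untouched, and `(config, seed)` reproduces a dataset
byte-identically.

Two practical notes on the generating distributions. First, $U(-1,1)$
correlations occasionally come close to $\pm 1$; the generator accepts the
full range but warns beyond 0.99. Second, the half-normal time
discrimination has substantial mass near zero, i.e. items with enormous
residual SD $\sigma_j$ whose RT parameters are only weakly identified: for
such items the posterior reverts to the prior and their squared errors
dominate aggregate RT-side MSEs, even though items with moderate
$\sigma_j$ are recovered an order of magnitude more precisely. Simulated
log times are clipped to $\pm 700$ so that the seconds-scale matrix stays
representable in double precision; the clip only ever binds for such
pathological items. For the same reason the recovery report evaluates the
"sigma" family on the time-discrimination ($1/\sigma$) scale — the scale
the parameter is drawn and assigned its prior on, and the one on which
the Monte-Carlo error is stable.

What the simulator does *not* emulate: conditional RA–RT dependence beyond
the latent structure, aberrant behaviors (speededness, cheating),
not-reached or omitted items, and non-lognormal time distributions. A
passing recovery study therefore demonstrates internal consistency of
model + sampler, not robustness to real-data violations.

## Recovery studies

`run_recovery_study()` crosses $(N, m)$ conditions with replications,
refitting fresh data each time (person correlations are redrawn every
replication and recorded — replications are draws from the design, not
repeats of one population). Point estimates are posterior means (EAP), the
conventional estimator for MSE tables. MSE and Bias divide by
$R \times$ (number of evaluated units): items for item families, examinees
for person families. Replication seeds derive deterministically from the
base seed and the (condition, replication) index and are logged per row.
Non-converged replications (any PSRF at or above 1.1) are excluded from
the summary by default, with a reported count; a flag retains them.

## Problem sizes used by the shipped studies

The package's reference checks run the main recovery condition at full
size, $N = 500$, $m = 30$ (three 10-item groups), with 2 chains × 500
NUTS iterations (half warmup) and 5 replications; trend checks use a
reduced grid ($N \in \{300, 600\}$, $m \in \{18, 36\}$, 2 replications),
model-selection recovery uses five datasets at $N = 200$, $m = 15$, and
interval-coverage checks use twenty datasets at $N = 150$, $m = 9$. These
sizes are the package's own choices balancing Monte-Carlo error against
desk-scale runtimes; the full crossed design at 30 replications is an
overnight batch job via the `recover` subcommand.

## Known limitations

* The sampler uses a diagonal mass matrix; extremely correlated item
  posteriors (tiny groups, few examinees) may need longer warmup or a
  higher `adapt_delta`.
* PSIS-LOO tail estimates degrade (Pareto $k > 0.7$) for highly
  influential cells, typically when a person × item time is extreme under
  an item with small $\sigma_j$; the warning names the count.
* Absolute RT fit indices are on the log-time scale (see above).
* The bi-factor orthogonality is an assumption, not an estimate: the
  model cannot represent correlated specific traits, and neither can the
  simulator.
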