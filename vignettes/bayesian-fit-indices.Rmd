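---
title: "Bayesian CFA fit indices: models, priors, and the simulation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian CFA fit indices: models, priors, and the simulation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsemfit)
```

## The model and the question

Confirmatory factor analysis relates p observed indicators to q latent
factors through

$$x = \tau + \Lambda \xi + \delta, \qquad
  \xi \sim N(\kappa, \Phi), \quad \delta \sim N(0, \Psi),$$

with $\kappa = 0$, $\Phi$ a correlation matrix (all factor variances fixed
to 1 for identification; loadings and correlations free), and $\Psi$
diagonal. The implied covariance is $\Sigma = \Lambda\Phi\Lambda' + \Psi$.

When such a model is estimated by MCMC, global fit is judged through
posterior functionals of the chi-square discrepancy

$$D(\theta) = N\left[\ln|\Sigma(\theta)| + \mathrm{tr}\,S\Sigma(\theta)^{-1}
  - \ln|S| - p\right],$$

the deviance against the saturated model. `bsemfit` implements the four
posterior fit measures built on it — the posterior predictive p-value
(PPp), two Bayesian RMSEA variants, BCFI, and BTLI — together with the
population models, prior families, Gibbs sampler, and Monte Carlo harness
needed to study how those measures respond to model misspecification,
sample size, model size, and prior informativeness.

Per retained draw $i$, with $p^* = p(p+1)/2$ unique covariance moments and
$pD = \bar D - D(\bar\theta)$ the effective number of parameters:

- $\mathrm{PPp} = m^{-1}\sum_i 1\{D_i^{obs} < D_i^{rep}\}$, where
  $D_i^{rep}$ is the discrepancy of a fresh dataset simulated at draw $i$;
- $\mathrm{BRMSEA}^{ppmc}_i =
  \sqrt{\max(0, ((D_i^{obs} - D_i^{rep}) - (p^* - pD))/((p^* - pD)N))}$;
- $\mathrm{BRMSEA}^{DevM}_i =
  \sqrt{\max(0, (D_i^{obs} - p^*)/((p^* - pD)N))}$;
- $\mathrm{BCFI}_i = 1 - (D_{H,i}^{obs} - p^*)/(D_{o,i}^{obs} - p^*)$
  against an independence null model $o$ (covariances fixed to zero, means
  and variances free);
- $\mathrm{BTLI}_i = (R_o - R_H)/(R_o - 1)$ with
  $R_\bullet = (D_{\bullet,i}^{obs} - pD_\bullet)/(p^* - pD_\bullet)$.

Rejection uses the posterior mean: BRMSEA > 0.06, BCFI/BTLI < 0.95, PPp
outside (0.05, 0.95). The 90% equal-tailed credible interval classifies
fit as good/poor/inconclusive (`decide()`).

### The discrepancy measures the covariance structure

The discrepancy series saturates the mean structure: the mean term of
$D$ is evaluated at the sample mean, so the series responds to the
covariance structure only. This choice is forced by internal consistency:
$p^*$ counts covariance moments only, and the benchmark identity
$pD \approx q$ under diffuse priors then holds with $q$ the free
covariance-structure parameters (loadings + factor correlations + residual
variances; 33 for the correctly specified three-factor model). With the
mean term left in, pD absorbs the p sampled intercepts, $p^* - pD$ is no
longer the model's degrees of freedom, and the Bayesian indices drift away
from their frequentist counterparts. Under the saturated-mean convention
the large-sample diffuse-prior indices agree with the frequentist
population values to within 0.01, which the acceptance tests verify
directly. Intercepts are still sampled with a
flat prior — they are part of the model, not of the fit statistic. The
same convention makes the null-model pD approximately p (its free
variances).

## Population models and misspecification

`build_generation_model()` constructs the data-generating models: families
A/B (3 factors, 5 items each; A varies the factor equicorrelation, B fixes
it at 0.5 and adds one cross-loading per factor), and the larger families
C1–C3 (independent-cluster, 3 or 6 factors, 5 or 10 items) and D1–D3
(with 6 or 12 cross-loadings) at correlation 0.85. Primary loadings follow
the (.70, .70, .75, .80, .80) block; ten-item factors repeat the block,
preserving the marginal loading distribution.

Three conventions were open and were frozen by requiring the ML population
fits to reproduce the study's reference population RMSEA/CFI/TLI values
at printed precision:

- **Residual variances.** $\psi_j = 1 - \sum_k \lambda_{jk}^2$: each
  item's residual subtracts the squared cross-loading as well as the
  squared primary loading, while the factor-covariance contribution
  $2\lambda_p\lambda_c\phi$ is not subtracted (full standardization is
  infeasible for a .80 primary with a .50 cross-loading). The alternative
  (subtracting only the primary loading) misses the family-B reference rows by
  up to 0.03 RMSEA; this convention reproduces all of them exactly.
- **Cross-loading placement and drop order.** Family B uses the printed
  positions (items 5, 9, 15 loading on the next factor cyclically). The
  D families place k cross-loadings per factor on the block's last
  (highest-loading) items. When a misspecified model ignores some
  cross-loadings, they are dropped in interleaved order — the first
  cross-loading of factor 1, then of factor 2, and so on — which
  reproduces the intermediate D rows exactly; dropping a whole factor's
  pair first does not.
- **Dimensionality misspecification.** Model A's two-factor form keeps
  whole blocks (items 1–5 vs 6–15; fifteen items cannot split evenly, and
  the study's reported convergence trouble with unequal items per factor
  corroborates the unequal split). The larger models split items into
  contiguous, as-equal-as-possible groups (30 items onto two 15-item
  factors; onto four factors as 8/8/7/7), which matches the reference
  values where factor merges do not. One non-sample-level row (the
  six-factor, five-item model fitted with four factors) remains 0.001–
  0.002 away from print under every allocation we tested; the reference
  population fits were computed from a simulated N = 1,000,000 dataset,
  which carries sampling noise of this order.

`fit_ml()` fits analysis models to covariance matrices by L-BFGS-B with an
analytic gradient, residual variances bounded at $10^{-6}$ and
correlations at $\pm 0.999$. Merged-factor models are multimodal — the
two-factor fit to the weakly correlated three-factor population has a
local optimum in which the merged factor's blocks load equally, above the
global discrepancy — so the optimizer always runs a deterministic battery
of 12 starts (the population-pattern start plus seeded uniform draws) and
keeps the best. Population fits plug
N = 1,000,000 into the index formulas and target the analytic population
covariance directly, which the simulated-large-N procedure of the original protocol
converges to.

## Priors

Five normal families on every free loading: Diffuse N(0, 1000); AlignedSV
N($\mu_\lambda$, 0.01) and AlignedLV N($\mu_\lambda$, 1) centered on the
population value; DivergentSV N(0.5, 0.01) and DivergentLV N(0.5, 1)
centered on a wrong-but-plausible value. For a loading with no population
counterpart (an item reassigned to a merged factor), aligned families
center on the item's population primary loading, preserving the
"accurate about magnitude" reading. Intercepts get an improper flat
prior. Residual variances use the limiting noninformative inverse-gamma
(shape −1, scale 0), giving the conditional IG(n/2 − 1, SSR/2); the factor
covariance uses the improper inverse-Wishart with zero scale and df
−(q+1), which enters through the parameter-expanded update below. These
are the stated software defaults; they can become unintentionally
informative when a variance approaches zero, which none of the study's
populations do.

## The Gibbs sampler

Each sweep draws, in order:

1. **Factor scores** from their exact multivariate-normal conditional
   (precision $\Lambda'\Psi^{-1}\Lambda + \Phi^{-1}$), all n rows at once.
2. **The factor correlation matrix** by parameter expansion: an
   unconstrained covariance $W \sim IW(\xi'\xi,\, n - q - 1)$ (the
   limiting improper prior makes the conditional proper for n > 2q), then
   $\Phi = \mathrm{cov2cor}(W)$ with the scales pushed into the loadings
   and factor scores. This preserves conjugacy under the unit-variance
   identification; a random-walk alternative was considered and rejected
   as slower-mixing.
3. **Per item**: the residual variance from its inverse-gamma conditional,
   then intercept and loadings jointly from the conjugate normal
   regression update (flat intercept prior, the loading prior as
   specified).

Chains start overdispersed: loadings at the prior mean plus alternating
offsets (±0.25, ±0.5, ...) per chain, residual variances at 1,
correlations at 0, intercepts at the sample means. Sign/label switching —
a real concern only under the sign-symmetric diffuse prior — is resolved
by per-chain reflection: any factor whose mean primary loading is negative
has its loadings and correlations flipped before convergence checks and
pooling, so mean primary loadings are nonnegative by construction.

Convergence follows the study protocol: the potential scale reduction
factor (classic Gelman–Rubin on the second half of each chain, floored at
1) must fall below 1.10 for every monitored parameter, checked first at
`min_iterations` and then on a geometric schedule (10% growth), up to
`max_iterations`. The first half of however many iterations were run is
discarded as burn-in; retained draws are the pooled second halves. The
production protocol is 3 chains with 10,000–500,000 iterations; the
package's desk-scale default for tests and the acceptance script is
3 × 2,000, which keeps every sampled model in this study's conditions
converging while a full fit takes seconds. Draws are stored densely, so
runs near the production maximum need memory proportional to iterations;
the harness is designed for the desk-scale settings.

## Synthetic data and the study grids

`generate_data()` draws i.i.d. multivariate-normal rows from the
population model's implied distribution — by construction exactly the
study's data-generating process (continuous indicators, zero means,
standardized factors). What it deliberately does not emulate: non-normal
or ordinal indicators, missing data, or correlated residuals, so passing
tests speak to the normal-theory behavior of the indices, not to their
robustness. Replication seeds come from a counter-based stream keyed by
(base seed, condition index, replication index), so any replication is
reproducible in isolation and non-converged replications are replaced by
advancing the replication counter without disturbing the others —
matching the protocol of generating more replications until the target
number of converged solutions is reached.

`build_condition_grid(1)` enumerates the 240 study-1 analysis conditions
(16 data-generation conditions × 3 analysis models × 5 priors; n in
{75, 200, 500, 2000}); `build_condition_grid(2)` the 72 study-2 conditions
(6 generation models × correct/most-severe analysis × n in {200, 500} ×
{Diffuse, AlignedSV, DivergentSV}).

## Evaluation harness

`run_condition()` runs the replications of one condition (generate → fit
hypothesized and null models → series → indices → decisions),
deterministically given a base seed. `summarize_study()` produces the
mean/SD, rejection-rate, credible-interval-classification, and convergence
tables; `eta_squared()` computes factorial-ANOVA effect sizes
($\eta^2 = SS_{effect}/SS_{total}$, flagged at 0.0588 and 0.1379). Because
the $\eta^2$ decomposition is only clean in balanced layouts, unbalanced
cells (after convergence filtering) are subsampled to the minimum cell
count with a fixed seed. Across-replication spread uses the sample
standard deviation (divisor n − 1).

## Numerical choices and degenerate inputs

- Divisor-N sample covariance throughout the Bayesian side; the ML
  chi-square uses (N − 1) · f_min, immaterial at the population N.
- 90% intervals are equal-tailed, linear-interpolation quantiles.
- BCFI draws are clamped to [0, 1] for summaries; BTLI is left unclamped
  (its frequentist counterpart can exceed 1). Draws with a null
  discrepancy equal to $p^*$ (BCFI) or $R_o = 1$ (BTLI) are flagged
  invalid and excluded from summaries.
- A non-positive-definite conditional anywhere in a replication aborts
  that replication, which is then treated exactly like PSR
  non-convergence: recorded and replaced.
- The saturated three-indicator one-factor model has zero degrees of
  freedom; `fit_ml()` reports NA for RMSEA/CFI/TLI there.

## What the tests and acceptance runs compute

The test suite reproduces the reference population fit values at printed
precision for every study-1 row and every sample-level study-2 row, and
the acceptance runs recompute two reference sample-level quantities at
desk scale (20 seeded replications, 3 × 2,000 iterations): the mean
posterior-mean BRMSEA (deviance form) for the one-factor fit to the
weakly correlated three-factor population at n = 200, and the mean
posterior-mean BCFI for the two-factor fit to the strongly correlated
population at n = 500. Property tests cover the index identities, the
discrepancy against an observation-wise likelihood-ratio oracle,
pD ≈ q under diffuse priors and its decline under small-variance priors,
large-n agreement between the Bayesian indices and the frequentist
population values, parameter recovery, and end-to-end determinism.

## Known limitations

Correlated residual structures, categorical indicators, and missing data
are out of scope. The production-scale run (240 conditions × 500
replications) is supported by the harness design (independent seeded
replications, replacement policy) but is a cluster-scale undertaking; all
shipped checks run at desk scale. The independence null model inherits the
conceptual awkwardness of a "null model with priors"; we follow the
noninformative-prior justification and fit it with its own exact conjugate
posterior of matched length, pairing draws by index — any consistent
pairing is admissible since BCFI/BTLI combine the two series only through
per-draw ratios of their own observed discrepancies, at the cost of some
Monte Carlo noise in draw-wise values but not in their means.
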