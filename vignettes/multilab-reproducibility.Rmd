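---
title: "Assessing multi-laboratory reproducibility of behavioral treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing multi-laboratory reproducibility of behavioral treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labrepro)
```

## The question

When the same standardized experiment is run in several laboratories, how
well does each replicate reproduce the collective result? `labrepro`
implements a three-stage answer for two-group treatment designs on
behavioral outcomes:

1. **Per-replicate estimation.** Each laboratory's treatment contrast
   $\beta_j$ is estimated with a model matched to the response type:
   ordinary least squares on a transformed continuous response, or a
   binomial-logit mixed model for repeated binary choices and per-dish
   counts.
2. **Pooling.** The per-lab contrasts are combined by a random-effects
   meta-analysis, $y_j \sim N(\mu, v_j + \tau^2)$, giving an overall
   effect $\mu$, its standard error, and the between-laboratory variance
   $\tau^2$.
3. **Classification.** Each replicate is scored against the pooled result
   on three criteria: $P_{sig}$ (significance status, and sign when both
   are significant, agree with the overall result), $P_{cov}$ (the
   replicate's CI$_{95}$ covers $\mu$), and $P_{acc}$ (both). By
   construction $P_{acc} \le \min(P_{sig}, P_{cov})$.

The package ships the per-laboratory effect table of a published
three-laboratory study of insect behavior (four outcomes across sawfly,
grasshopper, and flour beetle experiments) so the full classification grid
can be reproduced offline, plus a synthetic data generator so every stage
is testable without any external data.

## Per-replicate models

The three families mirror the three experiment designs
(`outcome_spec()` declares which applies):

* **Gaussian after transform** — one observation per individual. Durations
  are analyzed as $\log(y + 1)$ (post-contact immobility, 0–600 s),
  distances as $\sqrt{y}$ (0–144 cm). The contrast is estimated by OLS;
  CI and p-value use the $t$ distribution on the residual degrees of
  freedom, which matches the printed per-lab CI bounds better than a
  normal approximation.
* **Binary logit** — repeated binary choices per individual, with an
  individual-level random intercept:
  $\mathrm{logit}\,P(y_{it}=1) = \alpha + \beta x_i + u_i$,
  $u_i \sim N(0, \sigma_u^2)$. Fitted by the Laplace approximation
  (`lme4::glmer`); Wald-z inference.
* **Proportion logit** — per-dish counts out of a known number of
  scorable individuals, with a dish random intercept and an
  observation-level random effect (OLRE, one level per row) that absorbs
  overdispersion. The Pearson dispersion ratio
  (`overdispersion_ratio()`) diagnoses whether the OLRE is needed:
  correctly specified binomial fits have a ratio near 1.

Replicate significance for classification uses the replicate p-value
threshold $p < 0.05$, while *overall* significance is decided by the
pooled CI$_{95}$ excluding zero. These asymmetric definitions are kept
deliberately rather than unified, because they are the definitions under
which the shipped effect table's classification grid was produced.

The pooled consistency check is a likelihood-ratio test of the
treatment-by-laboratory interaction (`interaction_lrt()`): the pooled data
are fitted with and without lab-specific treatment terms (maximum
likelihood throughout) and $2\Delta\ell$ is referred to
$\chi^2_{k-1}$ for $k$ laboratories. Its size is verified by simulation:
over 1,000 null datasets at the default two-group scenario the rejection
rate at $\alpha = 0.05$ stays within $[0.03, 0.07]$.

## Random-effects pooling and the variance-interpretation flag

`pool_random_effects()` computes
$\hat\mu = \sum w_j y_j / \sum w_j$ with $w_j = 1/(v_j + \hat\tau^2)$,
$SE(\hat\mu) = (\sum w_j)^{-1/2}$, a Wald-z CI, and Cochran's $Q$ from
fixed-effect weights. $\tau^2$ is estimated by REML (bounded
one-dimensional optimization of the restricted log-likelihood, tolerance
$10^{-8}$, boundary solutions snapped to exactly zero) or by the
closed-form DerSimonian–Laird moment estimator.

One flag deserves explanation. Reconstructing the published pooled rows
from the published per-lab (estimate, SE) pairs succeeds — for all four
outcomes, to the printed precision — only when each printed SE value
enters the pooling directly as that replicate's sampling **variance**
$v_j$, not as $v_j = SE^2$. The conventional $SE^2$ choice visibly fails a
discriminating check: for the substrate-choice outcome it yields a pooled
SE near 0.11 where 0.26 was printed. Whether the original analysis
intentionally passed SEs as variances or the table column is mislabeled
cannot be decided from the printed numbers alone; both hypotheses produce
identical output. The package therefore exposes
`variance_interpretation = "se_as_variance"` (reproduction mode) and
`"se_squared"` (the statistically correct default for new analyses), and
every result records which mode produced it.

A second printed-number subtlety: the niche-choice pooled upper CI bound
is printed as `-0.00`, i.e., negative before rounding. `read_effects()`
preserves the sign as an IEEE negative zero and `ci_excludes_zero()`
treats such a bound as strictly negative, so the outcome classifies as
overall-significant — as it must for the published grid to reproduce.
Coverage is a closed-interval test (a CI bound exactly equal to $\mu$
counts as covered), and a p-value exactly at 0.05 counts as
non-significant; neither boundary occurs in the shipped table.

## The synthetic generator

`simulate_experiment()` generates multi-lab datasets with the statistical
structure of the three designs — not their biology. All archetypes share
the lab-level structure
$\alpha_j = \alpha + N(0, \sigma_{lab}^2)$ and
$\beta_j = \beta + N(0, \sigma_{slope}^2)$; a nonzero `lab_slope_sd` is
what creates a true treatment-by-laboratory interaction. Each laboratory
draws from its own seed substream, so adding a laboratory leaves existing
laboratories' data bit-identical.

* `gaussian_two_group`: responses are generated on the transformed scale,
  back-transformed, and truncated at the raw-scale ceiling. Truncated
  values are retained, not flagged, matching how capped durations were
  analyzed.
* `binary_repeated_choice`: 50 repeated choices per individual (10 days
  of 5 measurements), each independently scorable with probability
  `availability_prob`; unscorable rows carry `NA` responses.
* `dish_proportion`: at each of 14 time points the number of scorable
  individuals per dish is $\mathrm{Bin}(3, a_{trt})$ and successes are
  binomial with a fresh observation-level noise term per row, so the
  generated counts are genuinely overdispersed relative to the binomial.

Missingness is modeled as independent Bernoulli thinning because only
marginal scorability rates are available (15.1% for the grasshopper
choices, 33.4% for adult beetles on their feet); real missingness is
likely serially correlated within individuals, which the generator does
not emulate. Passing tests therefore demonstrate correct behavior under
independent thinning, not robustness to structured missingness.

Default scenarios (`default_scenario()`) use the published design sizes:
3 labs, 30 individuals per group per lab (continuous design), 31 per
morph per lab (binary choice), 18 dishes of 3 per life stage per lab
(proportion design), with treatment effects set to the published pooled
values. Two generator defaults were genuinely open and are worth
recording:

* The continuous-design baseline is $\alpha = 3.9$ on the $\log(y+1)$
  scale (median control duration about 50 s, lab shifts of SD 0.35). This
  keeps the 600 s ceiling rarely binding, so the fitted contrast is a
  consistent estimate of the generating $\beta$ — the property the
  recovery tests rely on. Pushing $\alpha$ toward the ceiling is the
  supported way to study truncation bias, but it is deliberately not the
  default.
* Between-lab heterogeneity defaults to zero (`lab_slope_sd = 0`,
  perfectly transferable effects), since no between-lab variance
  components are published; scenario files are explicit about every field
  so alternative regimes are one edit away.

## Verification strategy and problem sizes

The test suite checks each stage against an independent route:

* Laplace logistic mixed fits against a hand-written 50-node **adaptive
  Gauss–Hermite** marginal-likelihood maximizer on 12-unit, 10-observation
  datasets (agreement in the contrast to $10^{-3}$), and against plain GLM
  fits at the $\sigma_u = 0$ boundary (agreement to $10^{-6}$).
* DerSimonian–Laird $\tau^2$ against the hand closed form; REML $\tau^2$
  against a two-stage $10^4$-point grid search (to $10^{-4}$); pooling
  against `metafor::rma` as an independent cross-check.
* Rank-sum statistics against brute-force enumeration of all group
  assignments; the exact-p route is used for combined $n \le 20$ tie-free
  samples.
* Parameter recovery: 200 replicates per archetype at the default
  scenarios recover the generating effect with absolute bias below 0.05
  and pooled CI coverage within $[0.90, 0.98]$; the type-I error of the
  interaction LRT uses 1,000 simulations.

## Known limitations

* The Laplace approximation is accurate but not exact for Bernoulli data
  with few observations per unit: at 12 units × 10 observations and a
  random-intercept SD around 0.5–0.6, its contrast differs from 50-node
  adaptive quadrature by up to about $10^{-3}$ and its Wald SE by 1–2%.
  The SE agreement tightens as the variance component shrinks or the
  per-unit information grows.
* Estimation supports a single grouping factor plus an optional OLRE; no
  crossed random effects, no random slopes (random slopes exist only in
  the generator), and no small-sample df corrections for the mixed
  models (Wald-z inference).
* The meta-analysis is univariate: no meta-regression, no multivariate
  pooling, no publication-bias diagnostics.
* When classification is fed printed (rounded) numbers, comparisons use
  them as-is; no attempt is made to undo rounding beyond the signed-zero
  rule above.
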