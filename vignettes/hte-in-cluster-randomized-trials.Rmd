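---
title: "Detecting treatment-effect heterogeneity by aggregated subgroup variables in cluster-randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting treatment-effect heterogeneity by aggregated subgroup variables in cluster-randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crthte)
library(dplyr)
```

## The problem

In a cluster-randomized trial, intact groups — here, long-term care centers
— are randomized to intervention or control, and a key secondary question is
whether the intervention effect differs across subgroups (heterogeneity of
treatment effects, HTE). When the subgroup variable lives at the individual
level (say, a staff member's self-reported race) but the outcome is only
observed as a cluster-level rate, the analyst must aggregate the subgroup
variable to the cluster level — as a proportion, or as a high/low indicator —
and test an interaction between that aggregate and the intervention. This is
an ecological analysis, and effects estimated from aggregates need not equal
the individual-level effects of interest.

`crthte` implements a Monte-Carlo laboratory for this question. It generates
individual-level trial data under a known linear probability model,
randomizes clusters by constrained randomization, aggregates, fits a grid of
sixteen individual- and cluster-level regression models, and summarizes
type-I error, power, and bias of the HTE tests.

## The data-generating model

Each of $K$ centers ($K \in \{30, 40, 80\}$, 100 staff each) belongs to one
of two regions $R_c$ and is urban/suburban ($Z_{c1} = 1$) or rural. Each
staff member carries a binary self-reported race indicator $Z_{ci2}$
(1 = identifies as Black/African American). Outcomes are Bernoulli draws
from a linear probability model, so every coefficient is a risk difference:

$$
P(Y_{ci} = 1) = \beta_0 + \beta_{trt} A_c + \beta_{urb} Z_{c1}
 + \beta_{race} Z_{ci2} + \beta_{reg} R_c
 + \beta_{trt:urb} A_c Z_{c1} + \beta_{trt:race} A_c Z_{ci2}.
$$

The generating values, in probability units:

| parameter | value | meaning |
|---|---|---|
| $\beta_{trt}$ | 0.14 | intervention raises booster probability by 14 points |
| $\beta_{urb}$ | 0.03 | urban/suburban main effect |
| $\beta_{race}$ | 0.01 | race main effect |
| $\beta_{trt:urb}$ | 0.10 | intervention effect 10 points larger at urban centers |
| $\beta_{trt:race}$ | 0.15 | intervention effect 15 points larger for race = 1 |
| $\beta_0$ | 0.30 | baseline probability (default) |
| $\beta_{reg}$ | 0 | region effect (default) |

Nine named scenarios toggle the two subgroup main effects and the two
interactions (`scenario_table()`): scenario 1 is the global null apart from
the intervention effect, scenario 6 is the simplest scenario with race HTE,
scenario 9 turns everything on. A flag that is off forces the coefficient to
exactly zero, so null hypotheses are exactly true in null scenarios.
Construction validates that every implied probability on the binary
covariate support stays inside $[0, 1]$ (maximum under the defaults:
$0.30 + 0.14 + 0.03 + 0.01 + 0.10 + 0.15 = 0.73$).

Two defaults deserve comment, since the additive model makes them
consequential. The baseline $\beta_0 = 0.30$ is consistent with trial
eligibility restricted to centers with baseline booster rates of 60% or
less, and keeps all nine scenarios valid; the region effect defaults to 0,
but region is always retained as an adjustment covariate because it is a
randomization stratum. Both are configurable
(`true_coefficients()`).

## Constrained randomization

Centers are randomized half-and-half within each region, restricted to
allocations that balance urban/rural composition between arms. The balance
score is $\sum_r |u_{1r} - u_{0r}|$, the per-region absolute difference in
urban counts between arms. The acceptance rule retains every candidate
achieving the minimum observed score (exact balance whenever the composition
permits); a quantile rule (`acceptance = list(rule = "quantile", q = 0.1)`)
is available for heterogeneous compositions where exact balance may not
exist. When the number of stratified half-splits is no more than
`n_candidates` (default 50,000) the candidate set is enumerated
exhaustively; otherwise candidates are sampled. On the sampling path we draw,
for each candidate, the per-region count of urban clusters in arm 1 from its
exact hypergeometric distribution — the sufficient statistic for the score —
and realize the selected candidate as a uniform allocation given those
counts. This is distributionally identical to sampling whole allocations but
costs $O(\text{candidates})$ rather than $O(\text{candidates} \times K)$.
Under the default balanced composition the accepted set is large and
symmetric, so operating characteristics are insensitive to the
enumeration/sampling choice and to the cutoff; tests assert the score-0
guarantee and the uniform-selection property on enumerable cases.

## Aggregation

The cluster-level dataset carries the mean outcome $\bar{Y}_c$ and two
encodings of the race composition $V_c$ (the within-cluster proportion):

* the mean-centered proportion $V_c - \tfrac1K \sum_c V_c$, centered against
  the realized per-dataset mean so coefficients read as contrasts against
  the study-mean composition; and
* the indicator $I(V_c > t)$ with $t = 0.5$, using a strict inequality —
  a cluster exactly at 0.5 (possible with 100 staff) is coded "low".

## The model grid and inference

Sixteen least-squares fits per dataset (`model_grid()`): individual-level
models 1a–1f regress the binary outcome on intervention, urban, region, and
optionally the binary race variable and the `arm:urban` / `arm:race`
interactions; cluster-level models 2a–2j do the same for the cluster mean
outcome with race encoded as the centered proportion (2c, 2e, 2g, 2i) or the
indicator (2d, 2f, 2h, 2j). Point estimation is ordinary least squares —
identical to GEE with an identity link and independence working correlation.
Standard errors come from the cluster-robust sandwich
$(X'X)^{-1}[\sum_c X_c' r_c r_c' X_c](X'X)^{-1}$, multiplied by the
small-sample correction $K/(K-2)$ (two variables used in constrained
randomization). Wald statistics are referred to the standard normal by
default; a $t_{K-2}$ reference is available via `df_method = "t"` for users
who prefer a more conservative small-$K$ calibration, but all reported
results use the normal reference.

Degenerate dataset–model pairs — most commonly an indicator encoding that is
constant because every cluster falls on one side of the threshold — are
refused, flagged, excluded from that model's rejection-proportion
denominator, and counted in the `n_degenerate` column, rather than crashing
the study or silently contributing garbage.

## The simulation engine

`run_study()` executes scenarios × K × replications, fitting every requested
model per dataset and summarizing, per (scenario, K, model, coefficient):
rejection proportion with Monte-Carlo standard error
$\sqrt{\hat p(1-\hat p)/n_{\text{eff}}}$, mean and SD of the estimates, and
bias against the generating coefficient where a counterpart exists.
Cluster-level coefficients on aggregated race encodings have no generating
counterpart — that mismatch is the ecological-bias point itself — so they
are summarized by mean/SD only (`truth = NA`).

Reproducibility: each replication derives its seed from
(master seed, scenario id, K, replication index) through a fixed modular
recurrence (modulus $2^{31}-1$, prime, so seeds are distinct across
replication indices within a cell). Any cell can be recomputed in isolation,
and the output is bitwise invariant to the `workers` argument.

## What the generator does and does not emulate

The generator reproduces the structural features of a two-region,
urban/rural, 100-staff-per-center booster-vaccination trial: cluster-level
randomization with constrained balance, a binary individual covariate with
configurable prevalence, and risk-difference effects of realistic size. The
base composition is deterministic and balanced (half of clusters per region,
half urban within region, race prevalence 0.5 — a symmetric default that
maximizes information for the race-HTE contrast and keeps the 0.5-threshold
indicator non-degenerate). Three realism extensions relax it:

* **urban heterogeneity** — urban flags become independent Bernoulli draws;
* **race heterogeneity** — each cluster draws its prevalence from a Beta
  distribution with mean `p_race` and concentration 10 (a Beta-binomial
  over-dispersion mixture; as the concentration grows the scheme collapses
  to the fixed one);
* **baseline-boosted participants** — a fraction of individuals, independent
  of covariates, has the outcome forced to 1.

The heterogeneity mechanisms are the standard over-dispersion devices, chosen
here as reasonable stand-ins; the concentration default of 10 gives
cluster-level prevalence SD ≈ 0.15, a visibly over-dispersed but
non-degenerate composition. Not emulated: multiple follow-up timepoints,
missing outcomes, survey non-response (so aggregated race is measured
without error here — real aggregates built from voluntary surveys carry
representativeness error on top of everything studied), more than two race
categories (the compositional-data problem), and correlation between
baseline vaccination and covariates. Passing tests therefore speak to the
statistical behavior of the estimators under a clean version of the design,
not to robustness against those additional complications.

## Numerical and design choices

* Problem sizes: full operating-characteristic cells use 1000 datasets —
  Monte-Carlo SE at the 5% level ≈ 0.0069 — at K = 80 with 100 staff per
  cluster; the power-ordering comparison uses 300 datasets per cell, ample
  for a directional claim with power differences this large. Module-level
  tests use smaller K and cluster sizes.
* Estimator checks run against independent oracles: normal-equations OLS, a
  double-loop sandwich, exhaustive enumeration of stratified allocations.
* Rank-deficient or constant-column designs are flagged degenerate, never
  silently dropped or pseudo-inverted.
* The indicator boundary is strict (`>`); ties at the threshold go to "low".
* Odd region strata (not used by the defaults) assign the extra cluster's
  arm uniformly.

## Worked example

```{r example, eval = FALSE}
# one simulated trial under the simplest race-HTE scenario
trial <- simulate_trial(K = 80, scenario = 6, seed = 1)
fit <- fit_hte_model(trial$individuals, "1f")
tidy(fit)

# a small operating-characteristics run (200 reps for speed)
grid <- study_grid(scenarios = c(1, 6), K_values = c(30, 80), n_reps = 200,
                   models = c("1e", "1f", "2g", "2h", "2i", "2j"),
                   master_seed = 1)
oc <- run_study(grid)
compare_power(oc, term = "arm:race")
autoplot(oc, term = "arm:race")
```

The qualitative finding this machinery reproduces: individual-level models
control type-I error and have high power for race HTE, while cluster-level
models on aggregated race — especially the continuous-proportion encoding —
have inflated type-I error and uniformly lower power. If outcomes must be
defined at the cluster level, power to detect HTE by an aggregated
individual-level variable is often low even at K = 80; power calculations
for such analyses should simulate the individual-level data and aggregate,
exactly as done here, rather than simulate cluster-level data directly.

## Known limitations

* The linear probability model can, for extreme coefficient choices, imply
  probabilities outside $[0, 1]$; construction refuses such configurations
  rather than truncating, so some extreme scenarios are simply not
  representable.
* Bias summaries for cluster-level race coefficients are intentionally
  absent (no generating counterpart); comparisons across encodings should
  use rejection proportions and estimate distributions.
* The constrained-randomization acceptance cutoff matters only under
  heterogeneous composition; the quantile rule is provided but the package's
  reported results all use the minimum-score rule.
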