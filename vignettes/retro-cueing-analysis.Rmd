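---
title: "Modeling cross-modal retro-cueing detection experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cross-modal retro-cueing detection experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocue)
```

## The paradigm

`retrocue` implements the behavioral-analysis chain for a speeded go/no-go
detection paradigm in which a lateralized, spatially non-predictive auditory
cue is played before or after a near-threshold visual target presented in the
left or right periphery. The signed stimulus-onset asynchrony (SOA) between
cue and target takes the values −600, −150, +150 and +450 ms (negative =
pre-cue, positive = retro-cue), plus a no-cue condition; the cue is congruent
when it comes from the target's side and incongruent otherwise. The
scientific questions are whether a cue played *after* a faint target can
still improve its conscious detection (retro-perception across modalities),
and which latent component of the decision process any such effect loads on.

Each participant completes 20 blocks of 60 trials. The five cue conditions
split the 1,200 trials evenly (240 each); two thirds of each condition's
trials carry a target. Because SOA and congruency describe the *relation*
between cue and target, they are undefined whenever either stimulus is
absent: all 400 target-absent trials per participant form a single pooled
false-alarm stratum.

## The generative observer

`simulate_behavior()` uses an equal-variance Gaussian signal-detection
observer. On a target-present trial in cell $i$ the probability of a yes
response is $\Phi(d'_i/2 - c)$; on target-absent trials it is
$\Phi(-d'_0/2 - c)$ with a single baseline sensitivity $d'_0$, because those
trials belong to no condition cell. This symmetric-split convention is the
standard yes/no model and makes $d'$ recoverable by the analysis side. One
consequence worth stating explicitly: since target-absent trials share one
false-alarm rate, the *measurable* per-cell sensitivity is
$(d'_i + d'_0)/2$ — criterion-free but attenuated — so a condition
contrast of $\Delta d'$ in the generator appears as $\Delta d'/2$ in the
recovered table. `recover_effects()` reports its truth on this measurable
scale.

Hit response times are exact draws from a per-cell shifted-Wald
distribution; false-alarm RTs come from a separate parameter triple that no
analysis ever models (the reference literature does not report false-alarm
RT distributions, so these defaults are unconstrained). Two artifact
channels exercise the preprocessing rules: anticipations (a response RT
replaced by a uniform draw on [50, 150) ms, default rate 0.02) and
hardware-timing failures (trials pre-flagged for exclusion, default rate
0.01). Together these produce roughly 2% trial loss, consistent with the
"less than 3 ± 2%" loss the paradigm reports.

The default observer encodes the qualitative result pattern the package is
designed to study, chosen once as plausible magnitudes for near-threshold
audiovisual cueing and not revisited:

| cell | d′ | γ (1/s) | α | θ (s) |
|---|---|---|---|---|
| −600, both congruencies | 1.5 | 3.5 | 1.0 | 0.35 |
| −150 congruent / incongruent | 2.0 / 1.8 | 4.0 | 1.0 | 0.31 / 0.33 |
| +150 congruent / incongruent | 1.7 / 1.5 | 3.5 | 1.0 | 0.33 / 0.35 |
| +450, both | 1.5 | 3.5 | 1.0 | 0.35 |
| no cue | 1.5 | 3.3 | 1.0 | 0.36 |

with criterion $c = 0.15$ and $d'_0 = 1.5$. That is: a general sensitivity
and drift-rate boost for the short pre-cue, a spatial congruency advantage
at the two short SOAs carried by d′ and by a 20 ms shorter non-decision
time, and no condition effect on the decision threshold. Hit rates land
between 72% and 80%, matching the task's calibration target of ~75%, and
cells at the short SOAs average ~55 hits.

What the generator does *not* emulate: per-participant heterogeneity in
sensitivity, criterion or RT parameters (every simulated participant shares
the same truth, so between-participant spread is purely binomial/sampling);
sequential effects, learning or fatigue across blocks; fixation breaks and
their replay; the psychophysical staircase (a linear contrast→d′ map stands
in for demonstration of `adapt_contrast()` only). Passing tests therefore
show that the *estimators* behave correctly under the stated model, not that
real data satisfy that model.

## Detection sensitivity

`dprime()` computes $d' = Z(\mathrm{HR}) - Z(\mathrm{FAR})$. Extreme rates
are handled by the log-linear correction — 0.5 added to each of the four
counts — applied *always*, not only at 0/1, to avoid a discontinuity at the
boundary; raw rates remain available via `correction = "none"` and are what
the stored `hit_rate`/`fa_rate` columns report. Each cell's d′ pairs the
cell's hit rate with the participant's pooled false-alarm rate; pooling over
cue-present and cue-absent target-absent trials is the single biggest
analytic assumption and is forced by those trials belonging to no condition.

`rm_anova_2way()` is the classical fully-within two-factor decomposition,
each effect tested against its participant-interaction stratum.
Greenhouse–Geisser epsilon is computed from the covariance of the effect's
orthonormal contrast scores (for 2-level effects it is exactly 1) and the
corrected p-value is reported whenever epsilon < 1. Effect size is
generalized eta squared for a fully within design:
$SS_\text{effect} / (SS_\text{effect} + \sum SS_\text{subject strata})$.
Tests verify the F statistics against `stats::aov` error strata and against
a brute-force sums-of-squares oracle at 1e−9.

Condition contrasts use the percentile bootstrap (not BCa) of the paired
mean difference, resampling participants with replacement, 10,000 resamples
by default, at a Bonferroni-adjusted level $\alpha/m$. Percentile intervals
are simple, transformation-respecting and adequate for the smooth mean
statistics used here; they run slightly liberal at n = 20, which the test
suite's null-calibration check acknowledges with a wide acceptance band.

## Response times and inverse efficiency

Only hits are analyzed; false-alarm RTs are retained in the table but never
modeled. Medians per cell use the midpoint convention for even counts. The
inverse efficiency score divides *each* hit RT by the accuracy (hit rate) of
its participant × condition cell before averaging — division first, then
aggregation — yielding a cost measure in milliseconds that penalizes fast
but inaccurate cells. The pre/retro association is the Spearman rank
correlation between per-participant congruency effects (incongruent −
congruent mean IES) at −150 ms and at +150 ms; the two-sided p-value uses
the exact permutation distribution for n ≤ 10 without ties (the switch
point is an argument) and the t approximation otherwise.

## The shifted-Wald model

For a go/no-go task a two-boundary Wiener model is over-parameterized —
there is no second response to define a bias toward — so the RT model is the
single-boundary shifted-Wald (shifted inverse-Gaussian) distribution:

$$SW(t \mid \gamma, \alpha, \theta) =
  \frac{\alpha}{\sqrt{2\pi (t-\theta)^3}}
  \exp\!\left\{ -\frac{[\alpha - \gamma (t-\theta)]^2}{2(t-\theta)} \right\},
  \qquad t > \theta,$$

the first-passage time of a unit-variance Wiener process with drift $\gamma$
(evidence quality) to a single absorbing boundary $\alpha$ (response
caution), shifted by the non-decision time $\theta$ (encoding plus motor
time). Mean and SD are $\theta + \alpha/\gamma$ and
$\sqrt{\alpha/\gamma^3}$. Under $\mu = \alpha/\gamma$, $\lambda = \alpha^2$
the unshifted part is inverse-Gaussian, which gives a closed-form CDF
(evaluated with the exponential term in log space so large $\alpha\gamma$
cannot overflow), numeric quantiles by bracketed root-finding to 1e−12, and
exact sampling by the Michael–Schucany–Haas transformation method.

`simulate_diffusion()` is the package's independent brute-force oracle: an
Euler walk $dX = \gamma\,dt + \sqrt{dt}\,N(0,1)$ until $X \ge \alpha$. Its
empirical law converges to the analytic CDF as $dt \to 0$ (the acceptance
suite checks a Kolmogorov–Smirnov distance below 0.02 at $dt = 10^{-4}$ s
with $10^4$ walks); a step cap flags rather than truncates non-terminating
walks.

### Fitting

`fit_sw_mle()` maximizes the likelihood by profiling over $\theta$: for a
candidate $\theta$, the inverse-Gaussian MLEs on $x = t - \theta$ are closed
form ($\hat\mu = \bar x$, $\hat\lambda = n / \sum(1/x_i - 1/\hat\mu)$, then
$\hat\alpha = \sqrt{\hat\lambda}$, $\hat\gamma = \hat\alpha/\hat\mu$), so
only a one-dimensional search over $\theta \in (0, \min t - \varepsilon)$
remains, with $\varepsilon$ = 1 ms keeping every density finite. The profile
is usually unimodal but not guaranteed to be, so a 64-point grid locates the
basin and Brent refinement (`optimize`, tol 1e−9) polishes it. A
quantile-discrepancy objective (squared distance between empirical and model
deciles, same inner estimators) is exposed via `objective = "quantile"` as a
cross-check; the cited single-β quantile procedure from the methods
literature is not fully specified by its description, so the package commits
to the profile MLE as its reproducible definition of the same model.

Fits are per participant × SOA × congruency cell, short SOAs only by
default — with 20 participants, 2 × 2 × 20 = 80 individual distributions at
~55 hits per cell, above the minimum of 20 trials the fitter enforces
(configurable; adequacy claims in the simulation literature concern n ≈ 55).
At that cell size the per-cell $\hat\theta$ has a standard deviation around
50 ms; single-run group tables are therefore noisy, and effect conclusions
should come from `recover_effects()` aggregates or the ANOVAs, not from one
simulated experiment.

### Goodness of fit

The three-step descriptive battery: (1) QQ points of empirical order
statistics against model quantiles at positions $(i - 0.5)/n$, summarized by
a least-squares slope/intercept; (2) standardized decile residuals,
(empirical − model decile)/$SD(X)$ with $SD(X) = \sqrt{\alpha/\gamma^3}$
from the cell's own fit, which partially compensates for residual variance
growing with the data's spread; (3) per cell the sum Δ of the nine
residuals, and across cells its mean $\bar\Delta$, SD σ, 2.5–97.5% range,
and the Pearson correlation $\rho_{\Delta\sigma}$ between Δ and the cells'
$SD(X)$ — a check on whether $SD(X)$ worked as a standardizer. Both
$\bar\Delta$ and $\rho_{\Delta\sigma}$ should be near zero; warn flags fire
at |$\bar\Delta$| > 0.5 and |ρ| > 0.3 by default, configurable because the
criterion in the literature is only qualitative. Outliers are reported,
never removed, consistent with the no-upper-cutoff exclusion policy.

## Numerical and design choices

- **Units.** Trial tables carry milliseconds; everything inside the
  shifted-Wald module is seconds. `ms_to_s()`/`s_to_ms()` are the single
  documented boundary.
- **Exclusion rule.** "Under 150 ms" is strictly `<`; the cutoff applies
  uniformly to all responses, including false alarms (whether the original
  procedure did so for target-absent trials is unknowable from its
  description; uniformity is the simpler contract). No upper cutoff.
- **Empirical quantiles** use R's type-7 linear interpolation everywhere; the
  source material does not state a convention.
- **Integer balancing.** `build_design()` errors when counts cannot be split
  exactly (conditions, present/absent, congruency within SOA) rather than
  rounding, so fixture arithmetic is always exact. Within a congruency the
  left/right remainders are counterbalanced against each other so the side
  margin stays exact even when a quarter-split is impossible.
- **Seeds.** Every stochastic entry point takes a seed, preserves the
  caller's RNG state, and the pipeline derives fixed per-stage substreams
  from one master seed, so stages can be re-run in isolation.
- **Degenerate inputs.** All-equal RTs are a fit error; zero-accuracy IES
  cells are flagged and excluded from group means; identical Δ across cells
  makes $\rho_{\Delta\sigma}$ undefined and is reported as such; ANOVA input
  must be complete and balanced, and the pipeline drops participants with
  missing fitted cells (reporting how many) before the parameter ANOVAs.

## Problem sizes used by the tests

The test and acceptance suites size their simulations to exercise the
asymptotics without waste: distribution checks integrate 20 random parameter
triples to 1e−11; the diffusion–analytic comparison uses $10^4$ walks at
$dt = 10^{-4}$ s; MLE recovery uses $10^4$ exact draws (each parameter
within 5% relative error); the effect-recovery study runs 25–50 replicates
of the full 20-participant experiment, enough for the ~20 ms
non-decision-time congruency effect to be estimated with ~2 ms Monte-Carlo
error while leaving the θ-vs-α ANOVA power ordering clearly resolved.

## Limitations

- The pooled false-alarm rate halves generative sensitivity contrasts (see
  above); any real-data analysis inherits the same attenuation.
- No hierarchical or Bayesian estimation: cells are fitted independently,
  so per-cell parameter noise at n ≈ 55 is substantial and propagates into
  group summaries.
- The GLMM route of the original analysis chain (inverse-Gaussian mixed
  models with stepwise simplification and Tukey HSD) is deliberately out of
  scope; bootstrap contrasts are the supported inference path.
- The generator's lack of participant heterogeneity means between-subject
  correlation analyses (the pre/retro effect correlation) have no true
  effect to recover under defaults; the function is validated on constructed
  panels instead.
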