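# retrocue

Simulation and analysis of cross-modal cueing detection experiments:
paradigms in which a lateralized auditory cue precedes (pre-cue) or follows
(retro-cue) a near-threshold visual target at a signed stimulus-onset
asynchrony (SOA), and the question is whether — and through which latent
decision component — the cue changes detection of the target.

The package is aimed at cognitive psychophysicists working with speeded
go/no-go detection data. It provides, as one tested chain:

- a **synthetic experiment generator** with the standard design (20 blocks ×
  60 trials; SOAs −600/−150/+150/+450 ms plus no-cue, 240 trials each; 2/3
  target-present; exact congruent/incongruent and left/right balance) and a
  generative signal-detection observer with per-cell shifted-Wald response
  times, anticipation artifacts and timing failures;
- **preprocessing**: the strict `RT < 150 ms` anticipation exclusion (no
  upper cutoff) and assignment of every trial to exactly one analysis
  stratum — SOA × congruency cell, no-cue, or the pooled false-alarm pool;
- **signal-detection analysis**: per-cell `d′ = Z(HR) − Z(FAR)` with
  log-linear rate correction and pooled false alarms, two-way
  repeated-measures ANOVA with Greenhouse–Geisser correction and
  generalized eta squared, and Bonferroni-adjusted percentile-bootstrap
  contrasts (participants resampled, 10,000 draws);
- **response-time analysis**: per-cell median RT, the inverse efficiency
  score (each hit RT divided by its cell's accuracy), and the Spearman
  correlation between pre- and retro-cueing congruency effects;
- the **shifted-Wald (shifted inverse-Gaussian) distribution**

  `SW(t | γ, α, θ) = α / √(2π (t−θ)³) · exp( −[α − γ(t−θ)]² / (2(t−θ)) )`

  with density/CDF/quantiles/exact sampling, an Euler first-passage
  simulator as an independent oracle, profile maximum-likelihood fitting of
  the drift rate γ, threshold α and non-decision time θ per experimental
  cell, and the decile-residual goodness-of-fit battery
  (Δ, Δ̄, σ, ρ_Δσ, with residuals standardized by `SD(X) = √(α/γ³)`).

## Worked example

```r
library(retrocue)

cfg <- run_config(seed = 1)          # 20 participants, full design
report <- run_pipeline(cfg)

report$exclusions$fraction_excluded
#> [1] 0.02195833

report$sdt$anova
#>   effect             F     df_num df_den gg_epsilon  p_gg     gen_eta_sq
#> 1 soa_ms            19.57      3     57      0.875   5.4e-08     0.2004
#> 2 congruency         5.32      1     19      1.000   3.3e-02     0.0338
#> 3 soa_ms:congruency  2.71      3     57      0.902   6.0e-02     0.0391

report$sdt$contrasts[2, c("contrast", "mean_diff", "lower", "upper")]
#>   contrast               mean_diff lower upper
#> 1 cued(-150 ms) - no-cue     0.191 0.106 0.269

report$fit$n_cells_attempted
#> [1] 80
report$gof$delta_bar
#> [1] -0.01474750
```

Reading the output: ~2.2% of trials are excluded (anticipations plus timing
failures); detection sensitivity rises sharply for the short pre-cue — the
−150 ms cued-vs-no-cue bootstrap interval excludes zero while the other SOAs
do not — and a smaller congruency main effect is present. The 80 per-cell
shifted-Wald fits (2 SOAs × 2 congruencies × 20 participants) pass the
goodness-of-fit battery with a mean standardized residual sum near zero.
Single-run fitted parameters are noisy at ~55 trials per cell; use
`recover_effects()` to see the systematic picture:

```r
rec <- recover_effects(run_config(seed = 1), n_replicates = 50, seed = 2)
rec$summary[rec$summary$effect == "theta", ]
#>   effect truth mean_estimate      bias   rmse
#> 1 theta   0.02        0.0195 -0.000492 0.0107
rec$power
#> theta alpha
#>  0.44  0.04
```

The generator's 20 ms congruent reduction in non-decision time is recovered,
and the parameter ANOVAs flag the congruency effect on θ far more often than
on the (truly unaffected) threshold α.

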