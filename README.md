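# bancova

Robust Bayesian outcome analysis for three-arm pre–post anxiety trials:
a control arm, a conventional multiple-session exposure arm, and a
single-session exposure arm, each measured with questionnaire
instruments before an intervention and around a later test task. The
package is aimed at biostatisticians analysing (or planning) such
trials, where the questions of interest are posterior probabilities of
improvement and odds of improvement between arms rather than p-values.

## The model

For each outcome `y_i` an ANCOVA-style linear predictor relates the
mean to condition, the matching pre score `C_i`, their interaction, and
(for the speech-task outcomes) a familiarity covariate `F_i`:

    eta_i = mu + alpha_j + beta * C_i + gamma_j * C_i (+ beta_F * F_i)

with the control condition as reference (`alpha_1 = gamma_1 = 0` are
structural zeros). Questionnaire totals use a robust Student-t
likelihood, `y_i ~ t_nu(eta_i, sigma)`; the bounded IAT score is mapped
to the open unit interval and modelled as
`y_i ~ Beta(phi * mu_i, phi * (1 - mu_i))` with
`mu_i = logit^-1(eta_i)`. Priors are weakly informative: `N(0, 100^2)`
on every coefficient and `Gamma(2, 0.1)` on `sigma`, `nu`, `phi`
(central 95% interval 2.4–55.7). Posteriors are drawn with an adaptive
Metropolis sampler (4 chains x 3000 iterations by default), certified by
split-chain Rhat, and validated against a brute-force grid posterior.

From the fitted models the package derives, at scale-defined anchors of
the pre score (10% above the minimum, midpoint, 10% below the maximum):
the posterior probability of improvement
`P(post > x | pre = x)` (direction reversed for the
improvement-by-decrease scale), odds of improvement between arms,
slope-exceedance probabilities `P(beta + gamma_j > t)`, and classical
Cohen d effect sizes on change scores. Because no participant-level
dataset is public for this design, a first-class synthetic trial
generator reproduces the assumed data-generating process (arm sizes
15/14/16, heavy-tailed residuals, Beta-distributed normalized IAT) so
the full pipeline is testable end to end.

## Worked example

```r
library(bancova)

d <- generate_trial(paper_like_config(), seed = 1)
d
#> <trial_dataset: 45 participants (control n=15, multiple n=14, single n=16)>

fit <- fit_model(model_spec("postPRCA24"), d, seed = 1)
fit
#> <bancova_fit postPRCA24: 4 chains x 1500 kept draws, 8 parameters>
#>   max Rhat 1.007 (converged), mean acceptance 0.25

posterior_summary(fit)
#>        parameter    mean     sd    q2.5   q97.5 rhat    mcse
#> 1      intercept  29.202 15.795  -1.669 60.8100 1.00 0.54220
#> 2   arm_multiple -18.779 20.380 -60.107 20.2657 1.00 0.69436
#> 3     arm_single  15.601 20.414 -24.640 55.6064 1.00 0.69456
#> 4          slope   0.704  0.189   0.333  1.0745 1.00 0.00650
#> 5 slope_multiple  -0.326  0.249  -0.798  0.1795 1.00 0.00818
#> 6   slope_single  -0.452  0.248  -0.939  0.0352 1.00 0.00860
#> 7          sigma   7.926  0.991   6.202 10.1144 1.01 0.03459
#> 8             nu  24.969 14.229   6.330 59.8047 1.01 0.47798
```

PRCA-24 measures communication apprehension (24–120, lower is better),
so improvement at the highest anchor (110.4) is the posterior
probability that the modelled post mean falls *below* 110.4 given a pre
score of 110.4:

```r
x <- anchor_values(builtin_scales()$PRCA24)[["highest"]]  # 110.4
p_single  <- prob_improvement(conditional_mu_draws(fit, "single",  pre_value = x), x, "decrease")
p_control <- prob_improvement(conditional_mu_draws(fit, "control", pre_value = x), x, "decrease")
c(p_single, p_control)
#> [1] 1.000 0.734
odds_of_improvement(p_single, p_control)
#> [1] 1.362398
slope_exceedance(fit, "single", 1)   # P(beta + gamma_single > 1)
#> [1] 0
```

On this simulated trial the single-session arm is all but certain to
improve from a high baseline (probability 1.000 vs 0.734 for control,
odds 1.4), and its post-on-pre slope is almost surely below 1 — the
proportional carry-over of high baseline apprehension is reduced.
`improvement_report(fits)` assembles the full outcome x condition x
anchor grid plus pairwise odds, and `effect_size_table(d)` the
descriptive Cohen-d layer. The whole pipeline (simulate -> fit ->
report, with a manifest and MD5-checksummed artifacts) runs via
`run_pipeline()` or the thin CLI in `inst/cli/bancova`.

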