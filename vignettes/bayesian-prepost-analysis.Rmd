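---
title: "Robust Bayesian analysis of three-arm pre-post anxiety trials"
author: "bancova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian analysis of three-arm pre-post anxiety trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The design and the model

`bancova` analyses a three-arm trial of public speaking anxiety: a control
arm, a conventional multiple-session exposure arm, and a single-session
exposure arm, with questionnaire scores measured before the intervention
("pre") and before/after a test speech ("post"/"after"). Four instruments
are built in (see `builtin_scales()`):

* **IAT** — Implicit Association Test for fear of negative evaluation,
  scores in $[-2, 2]$, higher is better here (automatic self/liked
  association);
* **PRCA-24** — communication apprehension, scores in $[24, 120]$, the one
  scale where improvement is a *decrease*;
* **SPIC** — perceived index of competence, $[15, 105]$, measured both
  before (`postSPIC`, anticipatory) and after (`afterSPIC`) the test
  speech; higher is better;
* **STAI** short form, $[8, 32]$, coded so higher means more comfort;
  only measured before the speech, so it has no paired pre score.

For each outcome $y_i$ the mean is driven by the ANCOVA-style linear
predictor

$$
\eta_i = \mu + \alpha_j + \beta\, C_i + \gamma_j\, C_i \;(+\, \beta_F F_i),
$$

where $j$ indexes the condition, $C_i$ is the matching pre score, and
$F_i$ is an ordinal familiarity covariate (1..5) included for the two
SPIC outcomes and STAI, whose test task concerned a specific topic that
participants could simply know more or less about. The control condition
is the reference: $\alpha_{\text{control}} = \gamma_{\text{control}} = 0$
are structural zeros, not estimated parameters, so the treated arms are
contrasts against control. `postSTAI` has no covariate and reduces to
condition effects plus familiarity.

Two likelihood families are used:

* all questionnaire totals get a **location-scale Student-t**,
  $y_i \sim t_\nu(\eta_i, \sigma)$. The heavy tails absorb occasional
  outliers; for $\nu \gtrsim 30$ the fit is indistinguishable from a
  normal ANCOVA. Note $\sigma$ is the *scale*, not the SD: for finite
  $\nu$ the SD is $\sigma\sqrt{\nu/(\nu-2)}$.
* the bounded IAT score gets a **Beta regression with logit link**.
  Scores are affinely mapped to the unit interval and compressed away
  from the boundaries with $u' = (u(n-1)+0.5)/n$ (the standard
  Smithson–Verkuilen adjustment, applied everywhere so the map stays
  continuous and strictly monotone; `normalize_bounded()`). Then
  $y_i \sim \mathrm{Beta}(\phi\mu_i,\ \phi(1-\mu_i))$ with
  $\mu_i = \operatorname{logit}^{-1}(\eta_i)$, mean $\mu_i$ and precision
  $\phi$ — the shape parameterization is used verbatim, no alternative.

Priors are weakly informative and identical across outcomes: every
coefficient gets $\mathcal N(0, 100^2)$ (central 95% interval
$\pm 196$), and every positive parameter ($\sigma$, $\nu$, $\phi$) gets
$\mathrm{Gamma}(2, 0.1)$, whose central 95% interval is $(2.4, 55.7)$
(`prior_positive_interval()`). The degrees of freedom are continuous with
support $(1, \infty)$; the Gamma prior is truncated below 1 and
renormalized, which honours both the support statement and the prior
family. The five outcome models share no parameters: every reported
parameter set is outcome-specific, so the "joint" model is a product of
independent blocks and fitting them separately is exact.

# Derived quantities

**Anchors.** Conditional posteriors are evaluated with the pre score held
at three scale-defined anchors (`anchor_values()`): 10% of the range
above the minimum, the midpoint, and 10% below the maximum
(for PRCA-24: 33.6, 72, 110.4; for IAT: −1.6, 0, 1.6). Familiarity, where
used, is held at its median of 3.

**Probability of improvement.** For each condition and anchor $x$,
`conditional_mu_draws()` pushes every posterior draw through the linear
predictor and the link, and `prob_improvement()` reports
$P(\text{post} > x \mid \text{pre} = x)$ for improvement-by-increase
scales and $P(\text{post} < x \mid \text{pre} = x)$ for PRCA-24. The
probability is over the posterior of the *mean* (the conditional
regression line), not over a predictive draw — it quantifies the evidence
that the intervention shifts the expected outcome past the anchor. The
posterior-predictive variant is available via
`conditional_mu_draws(type = "predictive")` but is off by default. For
the Beta outcome the mean is mapped back to the raw IAT scale before
comparison, so anchors are used directly in score units. PRCA-24 is
reported at the middle/highest anchors, the improvement-by-increase
scales at lowest/middle, and `postSTAI` (no pre score) is compared
unconditionally against the same thresholds.

**Odds of improvement.** `odds_of_improvement()` is the plain ratio of
two arms' probabilities at the same anchor. A zero denominator yields a
labelled infinite-odds result. Display rounding (`format_odds()`) shows
integers from 10 upward and one decimal below, rounding half-to-even;
raw ratios are always retained, because ratios of *rounded*
probabilities can visibly disagree with rounded ratios of the exact
ones.

**Slope exceedance.** `slope_exceedance()` reports
$P(\beta + \gamma_j > t)$, e.g. the probability that post grows faster
than pre ($t = 1$) in a given arm.

**Effect sizes.** The descriptive layer (`effect_size_table()`) reports
change-score means and SEs per arm, paired Cohen $d$, and
between-arm Cohen $d$ on change scores. Paired $d$ defaults to the
change-score standardizer $d_z = \bar{d}/s_d$, the most common choice in
pre-post designs; the average-SD variant $d_{av}$ is available as an
explicit option and the two are never mixed. Between-arm $d$ uses the
pooled SD with no small-sample correction.
`cohen_d_from_summary()` rebuilds $d$ from published means/SEs/ns;
applied to exact summaries it equals the raw-data computation to machine
precision, while published two-decimal SEs limit agreement to a few
hundredths. The no-pre outcome `postSTAI` enters the between-arm rows
through its post scores, and has no paired $d$.

# Sampling and diagnostics

The posterior of each block is sampled by an adaptive random-walk
Metropolis over the package's own `log_likelihood()` + `log_prior()`.
Positive parameters are sampled unconstrained ($\log\sigma$,
$\log(\nu-1)$, $\log\phi$, with Jacobians). Two design details matter in
practice:

* **Preconditioning.** Uncentered ANCOVA designs (pre scores around
  55–80 score units) make the intercept and slopes strongly correlated a
  posteriori; a diagonal proposal mixes poorly. The initial proposal
  covariance is therefore the least-squares coefficient covariance
  (which captures exactly that correlation), refined during warmup by
  Haario-style empirical-covariance adaptation with a global step size
  tuned toward the 0.234 optimal acceptance rate. The proposal is frozen
  after warmup so the kept draws form a genuine Markov chain.
* **Warmup split.** Defaults are 4 chains of 3000 iterations; the
  iteration total is split evenly, 1500 warmup + 1500 kept per chain
  (6000 kept draws), the common probabilistic-programming default. Each
  kept iteration performs 4 Metropolis updates, trading a little CPU for
  markedly lower autocorrelation at a fixed output size.

Convergence is certified by split-chain $\widehat{R}$ (`rhat()`): each
chain is halved so within-chain drift is caught as well as between-chain
disagreement. The operational gate is $\widehat{R} \le 1.01$ for every
parameter; a fit failing the gate is *flagged* (and fails the pipeline's
exit gate) rather than silently returned or hard-erroring, so replicate
studies can count flags. Monte Carlo standard errors of posterior means
are estimated by batch means (batch length $\approx\sqrt{n}$, pooled
across chains).

Two independent routes validate the sampler. `grid_posterior()`
brute-forces any reduced model with at most three free parameters
(everything else held fixed via `fit_model(fixed = ...)`) on a dense
tensor grid with trapezoidal normalization, flagging grids that leave
more than 0.1% of mass on their edges; its marginal means/SDs must match
MCMC within Monte Carlo error. Independently, the test suite re-expresses
one Student-t block in an external Gibbs sampler (JAGS) and checks
agreement of the posterior means. The large-$\nu$ limit is also checked:
with $\nu$ fixed at 1000, the Student-t fit must agree with an explicit
normal-likelihood fit (`model_spec(..., likelihood = "normal")`, provided
exactly for this validation role).

# The synthetic trial generator

No participant-level data are distributed with this design, so the
generator (`generate_trial()`) is first-class: it draws trials with
exactly the structure the models assume, which is what makes every
downstream stage testable.

* Pre scores are truncated normal within their scale bounds (drawn by
  inverse CDF, so the RNG stream length is deterministic). Pre-score
  levels are not reported for this design — only change-score
  descriptives are — so the defaults (IAT 0.2 ± 0.6, PRCA-24 80 ± 12,
  SPIC 55 ± 14) were chosen once as plausible moderate-anxiety levels
  and are configuration, not estimates.
* Familiarity is ordinal on 1..5 with mode (and median) 3.
* Student-t outcomes add $\sigma\, t_\nu$ noise to the linear predictor
  and are clipped to the scale bounds. Clipping mildly distorts the
  likelihood at the edges; the default configurations keep it below 1%
  of draws, and recovery tests use such configurations.
* The IAT outcome is drawn from the Beta likelihood on the normalized
  scale — strictly inside $(0,1)$ — and mapped back to score units.

`paper_like_config()` reproduces the reported design: arm sizes 15/14/16
(45 participants), and condition effects/interaction slopes for the SPIC
outcomes set to the reported posterior means (multiple: 47.78 with slope
change −0.67 before the speech, 68.06/−1.02 after; single: 26.29/−0.33
and 51.42/−0.52). The IAT block is set to match the reported change-score
descriptives (mean changes of roughly +0.35/+0.30/−0.10 for
single/multiple/control and a between-arm $d$ near 0.6), and the STAI
block to the reported arm means (23.2/20.7/20.6).

`null_config()` is the no-effect baseline used for calibration: all
condition effects and interactions are zero and each post mean equals
the anchor when the pre score sits at the anchor. For the Student-t
blocks that is intercept 0, slope 1; for STAI (no covariate) intercept
20, its middle anchor; for the Beta block a unit logit-scale slope with
intercept 0 would *not* center the post mean at the anchor (the link is
nonlinear), so the block uses intercept −0.5 and slope 1, which places
$\eta = 0$ — normalized mean 0.5, i.e. raw IAT 0 — at the normalized
middle anchor.

**A calibration note.** Under the null, the *mean-based* improvement
probability is not expected to sit near 0.5 for a single dataset at any
sample size: $P(\text{mean} > x \mid \text{data})$ is approximately
$\Phi(z)$ with $z$ standard normal across replicate trials, i.e. close
to uniform — it measures evidence, and evidence fluctuates. The
*predictive* probability, by contrast, concentrates at
$1/2 + O(n^{-1/2})$. The calibration suite therefore checks the
predictive variant; the headline analysis keeps the mean-based
definition.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real trials: item-level questionnaire structure
(totals are continuous, not sums of Likert items), pre/post correlation
beyond what the linear predictor induces (change-score reports do not
identify it; it is a free configuration), session-by-session dynamics of
the multiple-session arm, dropout, and any dependence between the five
outcomes beyond shared covariates.

# Numerical choices and test scale

Degenerate inputs are rejected early: scales with $x_{\min} \ge
x_{\max}$, scores outside bounds (reported with row indices), unknown
condition labels, non-positive $\sigma/\phi$, $\nu \le 1$, empty draw
vectors, single-chain $\widehat{R}$. Zero change-score SD flags the
paired $d$ as undefined (`NA` with a warning) except in the exact
no-change case, which is 0 by definition. Ratios with a zero denominator
return labelled infinite odds.

The validation suite runs at sizes chosen to keep a full check under a
couple of minutes on one core while leaving comfortable statistical
margins: recovery at 500 per arm (truth within 3 posterior SDs;
50-replicate interval coverage with a conservative 80% gate), oracle
equivalence on 30-record reduced models within 2 Monte Carlo SEs, null
calibration at 300 per arm within (0.3, 0.7), and $\widehat{R}$
calibration on 4 × 1000 i.i.d. draws within (0.999, 1.01).

# Known limitations

* The sampler is a random-walk Metropolis: robust and fully
  reproducible, but with far lower effective sample size per iteration
  than a gradient-based sampler; very small scales or near-degenerate
  designs may need more iterations.
* Exact numeric reproduction of the published posterior summaries is not
  possible from this package alone: the raw participant data are not
  public, and published probabilities enter only as inputs to
  downstream arithmetic (anchor and odds checks).
* The Beta model conditions on the observed sample size through the
  boundary squeeze; refitting after adding participants slightly changes
  the normalization of *all* scores, which is inherent to that
  adjustment.
* Missing scores are dropped per outcome block with a warning, not
  imputed.
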