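---
title: "Methods: simulating and analysing weight-of-advice trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing weight-of-advice trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woasim)
```

## The problem woasim addresses

In a judge–advisor system (JAS) experiment a *judge* states an initial
estimate, receives an *advisor's* estimate, and states a final estimate;
decision power stays with the judge. woasim implements the computational
skeleton of a two-arm randomised JAS trial in which palliative-care
clinicians estimate the probability that an advanced cancer patient survives
two weeks (0–100% scale), receive advice framed either as the output of a
prognostic algorithm or as another clinician's opinion, and then revise their
estimate. Each participant judges five patient vignettes whose advice values
are fixed at 90, 90, 75, 75 and 50 percent survival and are presented in
random order.

Because no participant-level dataset from such a trial is freely available,
the package pairs the analysis pipeline with a synthetic-data generator that
has a *known* ground-truth advice-weighting process. Every inferential
component can therefore be validated by parameter recovery: simulate with
known weights, analyse, and check that the estimates return the truth.

## The weight-of-advice statistic

For a triple of initial estimate $i$, advice $a$ and final estimate $f$,

$$\mathrm{WOA} = \frac{f - i}{|a - i|},$$

interpreted as the fraction of the distance towards the advice that the
judge covered: 0 means the advice was fully discounted, 1 fully adopted.
Three processing rules apply, in this order:

* **Tie exclusion.** When $a = i$ the statistic is undefined; the record is
  excluded (per record, not per participant).
* **Capping.** Raw values above 1 (overshooting past the advice) are capped
  at 1.
* **Negative values.** The denominator is an absolute value but the numerator
  is not, so raw WOA is negative whenever the final estimate moves away from
  the advice — *and also* whenever the advice lies below the initial estimate
  and the judge moves towards it, because then $f - i < 0$ while
  $|a - i| > 0$. The stated range of the statistic is 0–1, so the default
  policy clamps negatives to 0. `truncate_woa()` also offers `keep` and
  `drop` policies for sensitivity work, and the raw value is always retained
  in the records.

The second consequence above matters for study design: a generative weight
$w$ is the estimand of mean WOA only on records where the advice exceeds the
initial estimate. This is why the identifiability and recovery experiments
(below) use an *advice-above-anchor* configuration.

For the ordinal sensitivity analysis, WOA values in $[0,1]$ are binned into
five ordered categories, left-closed and right-open except the last:
$[0,0.2)$, $[0.2,0.4)$, $[0.4,0.6)$, $[0.6,0.8)$, $[0.8,1]$.

A per-protocol filter excludes all records of any participant with fewer
than five completed vignettes.

## The synthetic-data generator

`sim_config()` fixes the whole generative process; `simulate_trial()` runs
it. The stages, with defaults and rationale:

* **Allocation.** Blocked 1:1 randomisation with block sizes drawn uniformly
  from {4, 6, 8} (the standard mixed-block scheme; the size sequence is the
  one genuinely open design choice and uniform random selection per block is
  the conventional one). Within every block exactly half the entries are
  algorithm-arm. Consequently the running arm imbalance never exceeds 4.
* **Covariates.** Profession (doctor 0.49, nurse 0.41, other 0.10), total
  experience (≤14 y 0.35, 15+ y 0.65), palliative-care experience (0.30,
  0.36, 0.34), age band, gender and work setting are drawn independently
  from the configured marginal proportions; a published joint distribution
  does not exist, so no correlation structure is imposed.
* **Initial estimates.** $i \sim \mathcal{N}(\text{anchor}_v, 19^2)$
  truncated to $[0,100]$ and rounded to whole percent. The default anchors
  (75, 70, 65, 60, 55, rising with advice strength) average 65, matching a
  plausible overall mean initial estimate of ~65%. Note that truncation at
  100 sits 1.84 SD above a 65 anchor, so the realised mean is ≈63.6, not 65.
  With probability `tie_probability` (default 0.05) a draw is replaced by
  the advice value exactly, to exercise the tie-exclusion rule.
* **Advice weights.** The mean weight is a function of arm and advice
  strength (default table: algorithm 0.48/0.36/0.50 and clinician
  0.31/0.27/0.37 at strengths 50/75/90 — higher weights in the algorithm arm
  everywhere, the intermediate 75% strength weighted least). A single
  participant-level deviation $b_j \sim \mathcal{N}(0, 0.2^2)$ is added and
  the result clamped to $[0,1]$; this is exactly the between-participant
  heterogeneity that the random-intercept analysis model targets, and 0.2
  gives an intraclass correlation of about 0.6 against the response noise
  below. Clamping (rather than renormalised truncation) is used because it
  distorts the mean weight least.
* **Final estimates.** $f = i + w\,(a - i) + \varepsilon$, truncated to
  $[0,100]$ and rounded. With `noise_scale = "gap"` (default),
  $\varepsilon \sim \mathcal{N}(0, (0.15\,|a-i|)^2)$ — that is, noise with SD
  0.15 *on the WOA scale*, which keeps the precision of a response
  independent of how far the advice happens to be from the initial estimate.
  An absolute percent-scale noise option exists (`noise_scale = "percent"`).
* **Dropout.** Each participant independently fails to complete with
  probability 0.124 (so an enrolled cohort of 323 leaves ≈283 completers); a
  uniformly chosen nonempty subset of their five records is marked
  incomplete.

All randomness flows from one master seed through named substreams
(allocation, covariates, schedule, responses, dropout), so identical configs
give byte-identical datasets and each component is independently
reproducible.

### What the generator does and does not emulate

It emulates the design: arms, blocking, the 2:2:1 strength mix, random
vignette order, Table-style covariate marginals, ties, and per-protocol
attrition. It does **not** model the clinical content of vignettes, the
prognostic algorithm behind the advice values, covariate–weight
correlations, digit preferences (clinicians favouring round numbers), or
heavy-tailed response behaviour. Passing recovery tests therefore shows the
*pipeline* is correct, not that real clinicians behave like the generator.

A practical consequence of the literal WOA formula: under the default
(study-emulation) anchors the advice can fall below the initial estimate, in
which case even perfect adherence yields a negative raw WOA that the clamp
policy sends to 0. Observed arm means of the emulation therefore sit below
the generative weights. The identifiability preset `recovery_config()`
instead places every anchor 30–35 points below its advice value
(55/50/40/35/20 against 90/90/75/75/50) so that $a > i$ essentially always
and mean WOA equals the generative weight; recovery experiments use it.

## The inferential models

### Random-intercept linear model

The primary analysis is
$y_{jt} = x_{jt}^\top\beta + u_j + e_{jt}$, with $u_j \sim
\mathcal{N}(0,\sigma_u^2)$ per participant and $e_{jt} \sim
\mathcal{N}(0,\sigma_e^2)$, accounting for the five repeated vignettes per
participant. `fit_random_intercept()` profiles the restricted likelihood
over the variance ratio $\lambda = \sigma_u^2/\sigma_e^2$: for fixed
$\lambda$, $\beta$ and $\sigma_e^2$ have closed GLS forms via the Woodbury
identity on each participant block, so the whole fit reduces to a bounded
1-D search on $\log\lambda$ (over $e^{-14}$ to $e^{14}$) followed by Newton
polishing to a relative gradient tolerance of $10^{-8}$. The
$\sigma_u^2 = 0$ boundary is evaluated explicitly and reported as a boundary
fit when it wins. This route was chosen over general-purpose optimisation
for determinism and because every piece (GLS, profile, likelihood) has an
independent closed-form or dense-matrix oracle to test against. REML is the
default, as usual for variance components; ML is available for
likelihood-ratio comparisons.

Inference is by Wald tests on the GLS covariance of $\beta$ (single
coefficients and joint term tests, e.g. an arm-by-strength interaction);
95% intervals are $\hat\beta \pm 1.96\,\mathrm{se}$. Reference levels are
the algorithm arm, doctors, the lowest experience bands and strength 50,
with treatment contrasts; strength is categorical because the weight given
to advice need not be monotone in its strength. Moderator analyses fit one
moderator-by-arm interaction at a time rather than one joint model, which
keeps each test interpretable marginally. `arm_difference()` wraps the
arm-only model and reports the clinician-minus-algorithm coefficient.

### Multilevel proportional-odds model

The sensitivity analysis models the five WOA categories:
$\Pr(Y_{jt} \le k \mid u_j) = \operatorname{logit}^{-1}(\zeta_k -
x_{jt}^\top\beta - u_j)$ with $u_j \sim \mathcal{N}(0,\sigma_u^2)$.
The marginal likelihood integrates $u_j$ by *adaptive* Gauss–Hermite
quadrature: each evaluation finds every participant's posterior mode by a
vectorised Newton search, rescales the nodes by the local curvature, and
accumulates in log space. Fifteen nodes are the default; on test fixtures
the log-likelihood changes by less than $10^{-6}$ when doubled to 31, so the
quadrature error is negligible at this cluster size. Thresholds are
parameterised as a first cutpoint plus log-increments (strictly increasing
by construction), the random-effect SD as $\log\sigma$, and the outer
optimisation is BFGS started from a plain proportional-odds fit. Line
searches that probe non-finite regions receive a large finite penalty.
If a category is absent from the data its thresholds are unidentifiable;
the fit merges it with a neighbour, warns, and records the merge in the
result.

With $\sigma$ fixed at 0 the model collapses to an ordinary
proportional-odds fit, which is tested against an independent direct
maximisation (`MASS::polr`) to $10^{-4}$.

## Validation experiments and problem sizes

The test suite runs, among others:

* exact identifiability: a noise-free advice-above-anchor trial of 60
  participants, where every WOA equals its generative weight and the fitted
  arm difference equals $w_C - w_A = -0.13$ to machine precision;
* parameter recovery: 50 trials of 284 participants with weights 0.44/0.31,
  WOA-scale noise 0.15, participant SD 0.2, 5% ties and 12.4% dropout; the
  mean fitted arm difference must land within ±0.02 of −0.13. (Boundary
  clamping at 0 and 1 biases the expectation to ≈−0.120, which the band
  absorbs; the bias was computed analytically from the normal tail formulas
  before the experiment was first run.)
* type-I error: 500 null trials (equal weights 0.37) of 60 participants;
  the arm Wald test at $\alpha = 0.05$ must reject between 3% and 8%;
* likelihood oracles: dense per-block multivariate-normal evaluation agrees
  with the structured likelihood to $10^{-10}$; balanced designs match the
  closed-form ANOVA/GLS estimator to $10^{-6}$; full fits match an
  independent mixed-model implementation (`lme4`);
* randomisation guarantees over 1000 seeds and uniformity of the vignette
  permutation distribution over 10,000 seeds.

These sizes (60–284 participants, 50–500 replicates) were chosen as the
smallest designs at which the Monte-Carlo error of each check is comfortably
below its assertion band.

## Known limitations

* The generator's independence assumptions (covariates independent of each
  other and of the true weight) are simplifications; moderator recovery
  experiments exercise the machinery, not realistic effect sizes.
* Negative-WOA handling in the source trials of this literature is rarely
  reported; the clamp default is a convention, and conclusions sensitive to
  it should be re-run under `keep` and `drop`.
* Only a participant-level random intercept is supported — no vignette
  random effects, no crossed structures, and no Bayesian fitting.
* The Wald intervals use the normal reference; with very few participants a
  small-sample correction (not implemented) would be preferable.
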