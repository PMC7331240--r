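---
title: "Quantifying retest variability in standardized behavioural assessments"
author: "retest package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retest variability in standardized behavioural assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retest)
```

## The model

Standardized assessment batteries (the motivating case is a robotic Kinarm
Standard Tests battery) report each behavioural parameter as a Z-score
against a normative cohort. When a stable individual is assessed twice,
the two scores differ by measurement noise, possibly shifted by practice.
`retest` works on the additive decomposition, per participant $i$,
parameter $p$ and session $j \in \{1, 2\}$:

$$x_{ijp} = s_{ip} + \delta_p \, 1[j = 2] + e_{ijp},$$

with a stable subject component $s_{ip} \sim N(0, \sigma_s^2)$, a
session-level error $e_{ijp} \sim N(0, \sigma_e^2)$, and a fixed learning
shift $\delta_p$. Everything the package estimates is a function of these
components:

* the difference score $d = x_{2} - x_{1}$ has SD
  $\mathrm{SD_{diff}} = \sqrt{2}\,\sigma_e$;
* the retest confidence interval is $\mathrm{CI} = 1.64 \cdot
  \mathrm{SD_{diff}}$, a one-tailed 90% band: about 5% of stable
  individuals worsen by more than CI, and 5% improve by more than CI. The
  multiplier is configurable (`threshold_config(ci_multiplier = 1.96)`
  gives the fully two-tailed variant appropriate when "changed in either
  direction" is the question);
* the significant-change threshold is $\mathrm{SC} = \sqrt{2} \cdot
  \mathrm{CI}$, because a change score compounds the error of two
  assessments;
* the consistency ICC is
  $\mathrm{ICC\text{-}C} = \sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$,
  estimated from the two-way subjects $\times$ sessions mean squares as
  $(MS_S - MS_E)/(MS_S + MS_E)$ for $k = 2$ sessions. The session main
  effect absorbs $\delta_p$, so systematic practice shifts do not deflate
  the ICC; they are tested explicitly instead.

Difference scores with $|d| > 3.2$ (roughly a 1-in-1000 event for
standard-Normal scores) are treated as outliers, excluded from every
downstream estimate, and counted in the report. The boundary is strict: a
difference of exactly 3.2 is retained.

### Choice of the ICC estimator

Two estimators are exposed. The default, `"variance_components"`, is the
standard two-session consistency ICC $(MS_S - MS_E)/(MS_S + MS_E)$, which
converges to $\sigma_s^2/(\sigma_s^2+\sigma_e^2)$ under the model above
(expected mean squares $E[MS_S] = 2\sigma_s^2 + \sigma_e^2$,
$E[MS_E] = \sigma_e^2$). A literal mean-square ratio
$MS_S/(MS_S + MS_E)$ is sometimes written down for this quantity; it is
retained behind `icc_formula = "literal_ms_ratio"` for fidelity
comparisons, but it is not the default because it returns 0.5 rather
than 0 when subjects do not differ at all, and so is not a variance
share. Both agree at the extremes (1 when error vanishes) and the tests
pin their respective large-sample values (0.5 versus 0.75 when
$\sigma_s = \sigma_e$).

### Learning effects and multiplicity

Learning effects are two-sided paired t-tests on the outlier-excluded
difference scores, one per parameter, at $\alpha = 0.05$. Because a full
battery tests well over a hundred parameters, raw p-values are corrected
with the Benjamini–Hochberg step-up procedure; the default family is all
parameters of the run (per-task families are available via
`fdr_family = "task"`). Both flags are reported: raw significance and
FDR significance, with $q \le \alpha$ as the rejection rule (equivalent
to the step-up criterion). Negative shifts mean lower — better — scores
at retest; both signs occur in practice (some tasks show score inflation
instead), which is why testing is two-sided.

### Trial-level (intra-subject) error

Trial-based tasks average 20–25 trials into a session score. The standard
error of that mean, $\mathrm{SEM} = \mathrm{SD(trials)}/\sqrt{n_t}$, is
computed per participant and session, pooled across the dataset, and
scaled by $\sqrt{2} \cdot 1.64$ so it lives on the SC scale. Pooling is
root-mean-square by default — SEMs are standard deviations of estimators
and combine in quadrature; arithmetic-mean pooling is available
(`pooling = "mean"`) for sensitivity analysis, and with homogeneous trial
noise the two differ negligibly. Under the generative model the pooled
SEM converges to $\sigma_t/\sqrt{n_t}$, so with trial noise of the
magnitude seen in practice the IS error sits at a few percent of SC:
trial averaging is not the dominant source of retest variability.

## Composite scores and the one-sided transform

Parameters whose impairment direction is one-sided are folded onto a
non-negative scale before aggregation:

$$\zeta = \sqrt{2}\,\mathrm{erfcinv}\!\left(\tfrac{1}{2}\,
  \mathrm{erfc}\!\left(z/\sqrt{2}\right)\right)
  = \Phi^{-1}\!\left(\frac{1 + \Phi(z)}{2}\right),$$

so that the median performer maps to $\zeta = 0.674$ and good performance
compresses toward 0. Two-sided parameters stay as Z-scores. The per-task
composite is the Euclidean (RSS) distance over all components — or the
Mahalanobis distance for the M-Score variant, with the reference
covariance ridge-regularized by $10^{-8}\,\mathrm{tr}(\Sigma)/d$ so
near-singular covariances stay invertible. Missing components are dropped
from the sum rather than imputed. The composite distance is then
re-normalized against a reference cohort (below) to give the Z-Task
Score, and folded once more by the same transform into the one-sided Task
Score.

A symmetric interval $z \pm \mathrm{CI}$ on the Z scale maps to an
asymmetric interval on the Task-Score scale: the bounds are the transform
evaluated at $z - \mathrm{CI}$ and $z + \mathrm{CI}$. The upper distance
always exceeds the lower one, both grow with $z$, and both asymptote to
CI for severely impaired scores. (An alternative printed form of this
interval, with the $\tfrac12$ added outside the erfc product, would
confine scores to $(-0.674, 0.674)$ and contradict both the coverage of a
Task Score of 1 and the asymptotic bound behaviour; the package treats it
as a typographical variant and uses the composition above.)

### The normalization loop

`fit_normalization()` converts raw values (or composite distances) to
Z-scores by iterating: shift to positivity by $1 - \min(x)$ if needed;
Box–Cox de-skew with the maximum-likelihood $\lambda$ (profile likelihood
over $[-5, 5]$, spline-refined grid via `MASS::boxcox`); standardize;
trim $|Z| > 3.29$ (the two-sided 0.001 tail); repeat until a pass trims
nothing, with a default cap of 10 iterations — in practice one or two
passes suffice, and the cap only guards against pathological ping-pong.
The fitted model is the final (shift, $\lambda$, location, scale) tuple,
so applying it to its own retained training data reproduces mean 0 / SD 1
exactly, and new values are scored reproducibly; values non-positive
after the shift cannot be Box–Cox transformed and return `NA` rather
than a fabricated score. Models serialize to key-value text so a
reference-cohort normalization can be frozen and shipped.

Degenerate inputs are rejected early: fewer than 10 finite values, or a
constant vector, raise errors rather than returning meaningless scales.

## Probabilistic classification

Given an observed score, an impairment threshold $T$ (default 1.64, the
95th percentile of healthy performance) and the parameter's CI, the score
axis splits at $T \mp \mathrm{CI}$ into *not impaired* / *possibly
impaired* / *impaired*; edge ties go to the more severe category. The
probability that the true score exceeds $T$ treats the latent score as
Normal around the observation with SD $\mathrm{CI}/1.64$ — the choice
that makes the region edges land exactly on 5% and 95% and the threshold
itself on 50%. The percentile statements are exact by construction; the
Normality of the latent score is an assumption, reasonable after
normalization. The same logic classifies change between two assessments
with $\pm\mathrm{SC}$ around the first score.

## The synthetic generator as study design

`simulate_assessments()` draws from exactly the model the estimators
assume, which is what makes ground-truth testing possible. Its defaults
describe a plausible healthy retest cohort for a robotic battery:

| setting | default | rationale |
|---|---|---|
| `n_participants` | 56 | typical per-task cohort of a retest study |
| `sigma_subject` | 0.7 | with `sigma_error`, ICC $\approx 0.66$ — mid-range of observed task reliabilities |
| `sigma_error` | 0.5 | implies CI $\approx 1.16$, inside the observed 0.6–1.6 span |
| `learning_shift` | $-0.2$ | a small practice benefit, matching typical mean learning effects |
| `sigma_trial` | 0.3 | puts the IS error at a few percent of SC |
| `outlier_rate` / magnitude | 0.005 / 5 | rare gross failures (distraction, hardware glitch) at session level |

The default battery mirrors the structure of a KST run: VGR/RVGR/PM with
20/24/25 trials per session (dominant and non-dominant variants), plus
the single-run tasks, mixing one- and two-sided parameters.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: post-normalization distributions are
exactly Normal (no residual skew or heavy tails), learning is a fixed
effect common to all participants (no fast/slow learners), trial noise is
independent of session error (no fatigue drift), and there is no age/sex
covariate structure. Estimator behaviour under those violations must be
judged separately.

## Numerical choices

* The folding transform is computed through the complementary error
  function in its lower-tail form, which stays accurate beyond $|z| = 6$;
  the naive quantile form $\Phi^{-1}((1+\Phi(z))/2)$ loses precision past
  $z \approx 4$ in double arithmetic, which the tests account for by
  checking the defining relation $\Phi(-\zeta) = \Phi(-z)/2$ in the tail.
* Impairment probabilities use the lower-tail Normal CDF so they remain
  strictly monotone far from the threshold instead of rounding to 0 or 1.
* Sample SDs use the $n - 1$ denominator throughout.
* Monte Carlo routines derive an independent substream per grid point
  from the master seed, so curves are reproducible point-wise regardless
  of grid composition or order.
* Text round trips: simulated datasets are written with 17 significant
  digits (bit-exact on re-read); human-facing manifests use 15.

## Problem sizes

The test suite exercises the estimators at the sizes where their
asymptotic targets are sharp enough to assert: moment recovery at
$n = 10{,}000$, ICC convergence at $n = 5{,}000$, parameter recovery at
$n = 2{,}000$ with 3-Monte-Carlo-SE tolerances, type-I calibration over
4,000–5,000 replicates, FDR behaviour over 20–40 replicates of a
167-parameter family, and the stability and Task-Score simulations at
their native 10,000 iterations. These sizes are the package's choices for
tight yet fast checks; all scale linearly if sharper tolerances are
wanted.

## Known limitations

* The simplified reference-cohort normalization stands in for full
  normative regression models (age, sex, handedness, platform); the
  package normalizes against a user-supplied reference sample instead.
* The consistency ICC deliberately ignores systematic session shifts;
  absolute-agreement ICC(2,1) is out of scope.
* Within-session learning curves (trial-order effects) are not modelled;
  trial series enter only through their SEM.
* Bootstrap or analytic confidence intervals on the ICC itself are not
  provided.
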