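---
title: "Methods: simulating and analysing the circular predictive-inference task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing the circular predictive-inference task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predinf)
```

## The task and its generative process

`predinf` simulates a circular predictive-inference ("particle catching")
task. On each trial a particle lands at a position $X_t$ on a 360-point
circle, drawn from a Gaussian with SD $\sigma_N = 12$ degrees around a
generative mean $\mu_t$, wrapped onto the circle and rounded to an integer
position. The mean is constant until a *change-point*, at which it is
re-drawn uniformly over the 360 positions. A session has 300 trials in 4
blocks of 75: one 150-trial *stable* stretch (hazard 0.025, exactly 4
change-points) and one *volatile* stretch (hazard 0.125, exactly 19),
in randomised order. Change-point positions are placed uniformly without
replacement over trials 2..150 of each stretch, with no minimum spacing;
block breaks do not reset the mean. The schedule is generated from fixed
change-point *counts*; the hazard value is what the learner assumes, and
the empirical hazard (4/150, 19/150) matches it by construction.

The participant places a bucket (an arc) on the circle edge before each
outcome and reports confidence on a 1--100 scale; catching the particle
(circular distance from bucket centre at most the bucket half-width,
boundary inclusive) gains 10 points, missing loses 10. The bucket arc
half-width is not a determinable constant of the original task; it defaults
to 25 degrees, chosen so a normative agent's hit rate is mid-range, and it
is a configuration field — every hit-dependent quantity inherits it.

Positions live in $[1, 360]$, signed circular differences in
$(-180, 180]$ (the antipode resolves to $+180$), and distances in
$[0, 180]$.

## The reduced Bayesian change-point learner

The learner keeps a point estimate $B_t$ of the generative mean and updates
it with a delta rule,

$$B_{t+1} = B_t + \alpha_t\,\delta_t, \qquad \delta_t = X_t \ominus B_t,$$

where $\ominus$ is the signed circular difference and the dynamic learning
rate combines change-point probability $\Omega_t$ (CPP) and relative
uncertainty $\tau_t$:

$$\alpha_t = \Omega_t + (1-\Omega_t)\,\tau_t.$$

Model confidence is $\nu_t = 1 - \tau_t$; the regression-facing *relative
uncertainty* variable is $RU_t = (1-\Omega_t)\,\tau_t$, so that
$\alpha_t = \Omega_t + RU_t$ identically — a property the evidence-model
tests exploit.

CPP is the posterior probability that the latest outcome came from a
re-sampled distribution:

$$\Omega_t = \frac{\tfrac{1}{360}H}
{\tfrac{1}{360}H + \mathcal{N}(\delta_t;\,0,\sigma_t^2)\,(1-H)},$$

with $H$ the assumed hazard (the task block's true hazard, 0.025 or 0.125)
and predictive variance

$$\sigma_t^2 = \sigma_N^2 + \frac{(1-\nu_t)\,\sigma_N^2}{\nu_t}
            = \frac{\sigma_N^2}{\nu_t}.$$

Uncertainty propagates as a variance ratio,

$$\tau_{t+1} = \frac{\Omega_t\sigma_N^2 + (1-\Omega_t)\tau_t\sigma_N^2
  + \Omega_t(1-\Omega_t)\big(\delta_t\nu_t\big)^2}
 {\Omega_t\sigma_N^2 + (1-\Omega_t)\tau_t\sigma_N^2
  + \Omega_t(1-\Omega_t)\big(\delta_t\nu_t\big)^2 + \sigma_N^2}.$$

The three numerator terms are the estimation variance conditional on a
change-point, conditional on no change-point, and the variance induced by
not knowing which occurred; the extra $\sigma_N^2$ in the denominator is
outcome noise. Written this way the recursion *must* yield uncertainty, not
confidence: it resets to $1/2$ after a certain change-point
($\Omega_t = 1$) and decays as $\tau/(1+\tau)$ when $\Omega_t = 0$. This
direction is the only one mutually consistent with the predictive-variance
and learning-rate equations (both of which need confidence $\nu = 1-\tau$),
and it reproduces the expected qualitative behaviour — confidence is low
right after change-points and grows as evidence accumulates. The same
ratio is sometimes written with the confidence symbol on the left-hand
side; we treat that as a labelling slip and define the model consistently.

Numerical choices:

* the Gaussian density in CPP is the plain (unwrapped) normal evaluated at
  the signed circular error — no wrapped-normal correction. Errors large
  enough for wrapping mass to matter already drive $\Omega \to 1$, and the
  learner's behaviour is insensitive to the correction at $\sigma_N = 12$;
* $\nu$ is floored at $10^{-6}$ in the predictive variance, so the first
  trial ($\tau_1 = 1$) is well-defined;
* $B_1$ is initialised at the first outcome ($\delta_1 = 0$), and the first
  trial contributes no update row to analysis tables;
* CPP saturates to exactly 1 in double precision for $|\delta| \gtrsim 90$
  at $\sigma_N = 12$; monotonicity of $\Omega$ in $|\delta|$ is therefore a
  strict property only below saturation.

## The synthetic cohort

No generative behavioural model of participants is implied by the analyses
this package implements; the cohort generator is an artifact construct,
built so that every analysis stage has a known ground truth.

Each of $n = 437$ subjects (the analysis-sample size the generator mirrors)
receives an independent session and learner trace, plus standardized
dimension scores (AD, CIT, SW) drawn from a multivariate normal whose
default pairwise correlations (0.52, 0.43, 0.34) span the moderate band
reported for these factor scores, and independent standardized age and IQ
with a Bernoulli(0.42) female indicator. An *effect map* shifts each
subject's agent parameters linearly in their dimension scores; its default
signs and sizes mirror the reported moderation structure (CIT: confidence
intercept $+6.74$ units/SD, coupling $-1.57$ degrees/SD, evidence weights
on confidence $-1.5$ units/SD each; AD: confidence $-3.42$ units/SD;
SW: $+0.05$ gain on $|PE^b|$ in the action). These sizes are configuration,
not empirical claims; they place the simulated moderation statistics near
the reported significance tiers at $n = 437$ (the SW action effect
deliberately sits at a borderline tier).

The agent generates, per trial:

* **confidence** $c_{t+1}$, a clipped, rounded linear read-out of trial-$t$
  evidence — intercept minus weighted within-session z-scores of CPP, RU
  and $|PE^b|$, plus a hit bonus and Gaussian report noise;
* **action**: the bucket moves along the sign of $\delta_t$ by
  $\alpha_t|\delta_t| + g_{sw}|\delta_t| - \kappa\, z(c_{t+1}) + \epsilon$,
  clamped at zero and wrapped.

Coupling is *additive*: $\kappa$ is in degrees per confidence SD, directly
comparable to the coupling slope the regression estimates (default 8.85,
mirroring the headline within-subject effect). Confidence is standardized
inside the simulation with a deterministic reference scale derived from the
agent's parameters, because the empirical within-subject z-score does not
exist until the session is complete (confidence, action and hit feedback
form a sequential loop); the analysis side z-scores empirically.

Two intentional non-linearities shape what "recovery" means here. The
magnitude clamp at zero and the 180-degree wrap make the marginal
regression slope on confidence equal to $\kappa$ shrunk by the fraction of
trials on which neither binds (about 0.7--1.0 depending on configuration),
and the 1--100 confidence clipping mildly attenuates injected intercept
effects. Recovery tests therefore assert exact recovery only on noiseless
linear data, and analytic shrinkage bands or 2-SE coverage with a small
clipping allowance on simulated cohorts. Because confidence is driven by
the same evidence that drives the normative update, the marginal coupling
slope in the default cohort is *more* negative than $\kappa$ — the same
confounding present in real data, where confidence and surprise co-vary.

What the generator does **not** emulate: reaction times, slider dynamics
and anchoring on the 25/75 start values, questionnaire-level measurement
error in the dimensions (scores are sampled directly; the item pathway is
exercised separately by the factor-scoring fixture), attrition, or any
participant-level data-quality exclusions. Passing recovery tests show the
pipeline estimates what the generator encodes — they are evidence about
the software, not about human behaviour.

## Derived behaviour metrics and exclusions

Per update step $t \to t+1$: `action` $= |B^{subj}_{t+1} \ominus
B^{subj}_t|$, the signed update, the subjective prediction error
(outcome minus bucket), and the human learning rate
$LR^h = $ signed update / signed PE. Trials with $PE = 0$ are undefined and
flagged `zero_pe`; trials with $LR^h$ above the pooled dataset's 99th
percentile (a realisation of the data, not a constant; computed after
removing zero-PE trials, one-sided upper cut) are flagged `lr_outlier`.
Updates spanning block breaks are flagged and retained by default, with an
option to exclude. Exclusion is idempotent, and the excluded fraction is
reported alongside the threshold. Within-subject z-scores (confidence for
the coupling model; evidence predictors for the confidence evidence model)
are computed over each subject's included trials.

## The regression suite

All models are linear mixed-effects fits (REML, `bobyqa`), with
standardized age/IQ, binary gender, and standardized between-subject
moderators; moderators are z-scored using one value per subject:

* **coupling**: `action ~ z_conf + covariates (+ moderators +
  moderator:z_conf)`, random intercept and confidence slope per subject;
* **levels**: raw confidence (1--100) or action on moderators and
  covariates, random intercept;
* **evidence on action**: `action ~ |PE^b| + |PE^b|:CPP + |PE^b|:RU +
  |PE^b|:Hit` on the raw scale (every term except $|PE^b|$ through its
  interaction), random intercept;
* **evidence on confidence**: raw confidence on within-subject z-scored
  $|PE^b|$, CPP, RU plus Hit, no $|PE^b|$ interactions, random intercept.

Two moderator regimes mirror the reported analyses: each questionnaire
score in a separate model (Bonferroni $m = 9$), or the three dimensions
jointly ($m = 3$); both produce identical fits when only one moderator
exists. Evidence models use random intercepts only (random slopes are
specified explicitly only for the coupling model); moderator-by-slope
random terms are not estimable in this design and are fixed-only.

Inference is Wald with the normal approximation: $CI = \beta \pm 1.96\,SE$
on the classical SEs, raw and Bonferroni-adjusted p-values
($p_{adj} = \min(1, m\,p)$). Subject-clustered heteroskedasticity-consistent
SEs are reported alongside: for mixed fits the GLS sandwich with per-subject
meat blocks built from marginal residuals (random-effect covariance inverted
via the Woodbury identity, singular covariances ridged at $10^{-10}$ scale,
and a $J/(J-1)$ small-sample factor); the same estimator on an `lm` fit
reduces to the standard CR0/CR1 cluster sandwich, which is the independent
cross-check used in the tests. White's test is the textbook auxiliary
regression of squared residuals on predictors, squares and cross-products
($LM = nR^2$, chi-square with the rank of the auxiliary design); exact fits
and constant residuals return a zero statistic. A boundary (singular)
random-effects fit — expected here, since the generator puts no residual
between-subject variance on the coupling slope beyond the dimension
effects — is reported as converged-but-singular, not as a failure.

Moderation sizes are summarised as percent change of the main effect per
moderator SD, $100\,\beta_{int}/|\beta_{main}|$; a positive interaction on
a negative main effect is attenuation.

## Factor scoring

Item tables (subjects by 209 labelled items from the nine instruments) are
column-standardized and multiplied by an externally supplied 209 x 3
weight matrix, joined on item labels so column order is irrelevant;
standardization makes the scores scale-free. The transformation applied by
the original weight pipeline is not determinable from the analyses this
package reproduces; column standardization is the conventional choice and
is documented as an assumption. The published weights are external data:
the repository ships only a synthetic fixture whose per-item loadings are
calibrated (latent correlations 0.52/0.46/0.38, slightly above the target
band to offset item-noise and 5-point discretisation attenuation) so that
induced factor-score correlations land inside 0.34--0.52.

## Problem sizes used by the test suite

The package's own verification choices, balancing statistical resolution
against a test run of a few minutes: desk-scale statistics use 5,000
outcome draws and 2,000-subject score samples; full-scale recovery runs 5
replicates of the complete pipeline at 437 subjects x 300 trials, requiring
every configured moderation direction in every replicate (20/20 sign
checks); the null calibration uses 10 zero-effect cohorts of 100 subjects
and bounds the Bonferroni-corrected false-positive rate by the nominal
level plus twice its Monte-Carlo SE. Unit tests use 30--150-subject
cohorts.

## Known limitations

* The bucket half-width (and hence hit rates and everything downstream of
  `Hit`) is a package default, not a reproduced task constant.
* The agent's confidence mechanism is one admissible construction; real
  confidence reports have autocorrelation, anchoring and idiosyncratic
  scale use that the generator omits.
* p-values use the normal approximation rather than Satterthwaite or
  Kenward-Roger degrees of freedom; with hundreds of subjects the
  difference is negligible, with few subjects it is anticonservative.
* The cluster-robust estimator treats the estimated random-effect
  covariance as fixed when building $V_j$.
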