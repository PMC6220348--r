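---
title: "A state-space account of drift and washout under a visuomotor rotation"
author: "vmradapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-space account of drift and washout under a visuomotor rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmradapt)
```

## The phenomenon

When cursor feedback of a fast shooting movement is rotated 45 degrees
counter-clockwise and the mover is told to counter it by aiming at a
neighboring target 45 degrees clockwise, performance is initially perfect:
the explicit strategy cancels the rotation exactly. Yet over the following
trials the cursor *drifts* clockwise away from the target, even though the
task error started at zero. When the strategy is later abandoned, strong
after-effects appear and decay over the washout trials. The drift is the
signature of an implicit process that keeps learning from the *sensory
prediction error* (SPE) — the mismatch between where the cursor appeared and
where the forward model predicted it would appear — regardless of task
success.

`vmradapt` implements a minimal single-state model of this process, a
synthetic cohort generator that emulates the four-condition target-removal
experiment used to dissociate SPEs from performance errors, and the
statistical pipeline used to analyze such experiments.

## The model

All angles are in degrees, counter-clockwise positive, with the main target
defining 0. On trial $t$ the learner holds an internal estimate
$\hat{p}_t$ of the perturbation and

$$
\begin{aligned}
u_t &= -\hat{p}_t + S_t + n^u_t        &\text{(motor command)}\\
c_t &= u_t + p_t + n^p_t               &\text{(cursor feedback)}\\
\hat{h}_t &= u_t + \hat{p}_t           &\text{(forward-model prediction)}\\
\varepsilon_t &= c_t - \hat{h}_t = p_t + n^p_t - \hat{p}_t &\text{(SPE)}\\
\hat{p}_{t+1} &= a\,\hat{p}_t + b\,\varepsilon_t &\text{(memory update)}
\end{aligned}
$$

with retention rate $a$, learning rate $b$, motor noise
$n^u_t \sim N(0, \sigma_u^2)$ and perturbation noise
$n^p_t \sim N(0, \sigma_p^2)$. $S_t$ is the explicit strategy-plus-correction
term (e.g. $-45$ when aiming at the clockwise neighbor).

The model's central property is visible in the SPE line: the motor command
cancels out of $\varepsilon_t$, so **the memory update is independent of what
the hand actually did** — of the strategy, of deliberate corrections, and of
whether any target was visible. Two consequences follow and are enforced as
tests:

* with the strategy engaged and full retention ($a = 1$), the cursor error
  converges to the full rotation magnitude (the drift's fixed point);
* during washout ($p_t = 0$, $S_t = 0$) the error decays geometrically,
  $e_t = -\hat{p}_0 (a-b)^t$, so a fitted exponential time constant
  satisfies $\tau = -1/\ln(a-b)$.

Update timing follows the usual trial-wise convention: the estimate used for
the prediction and the command on trial $t$ is the value produced after
trial $t-1$'s feedback. On trials without any cursor there is no SPE, so
only retention applies, $\hat{p}_{t+1} = a \hat{p}_t$ (per trial, not per
second; the no-feedback block is short enough that the distinction is
immaterial at the rates used here). Angle arithmetic inside the model is
linear — modeled angles never approach the ±180 cut — and wrapping to
$(-180, 180]$ happens only at the analysis boundary.

```{r fixed-point}
params <- model_params(a = 1, b = 0.1, sigma_u = 0, sigma_p = 0)
out <- simulate_phase(data.frame(p = rep(45, 200), S = rep(-45, 200)), params)
round(out$c_obs[c(1, 10, 50, 200)], 2)  # drift towards -45
```

## The synthetic cohort

`simulate_cohort()` generates seeded participants for the four feedback
conditions of the 2×2 target-removal design: after movement onset the main
target, the neighboring target, both, or neither remain visible
(conditions 3/2/1/4 keep PE1-only / PE2-only / both / neither available;
the labeling follows the convention used consistently in the source
experiment's introduction, results and figures — its methods section states
the 2/3 labels the other way around, an internal inconsistency we resolve in
favor of the majority usage).

The schedule and calibration constants are those of the experiment being
emulated: blocks of 110/40/2/198/10/80 trials; 8 targets 45 degrees apart on
a 5.3 cm circle, each target appearing once per aligned 8-trial window;
rotation $45 + N(0, 0.5^2)$ degrees on rotation trials; motor noise
$\sigma_u = 6.1$ degrees, which calibrates the baseline trial-by-trial error
SD to its observed value; 13 participants per condition.

Choices the source leaves open were fixed once, as follows:

* **Learner heterogeneity.** $a = 0.98$ for everyone; $b \sim U(0.008,
  0.020)$ per participant. These give an asymptotic drift of 13–22 degrees
  over 200 adaptation trials and washout time constants of 25–35 trials —
  the order of magnitude seen in this class of experiment — plus enough
  between-participant spread for the end-drift ↔ after-effect association to
  exist in conditions 2/4.
* **Corrections.** Where PE1 (the cursor-to-main-target error) is visible,
  participants integrate it: the correction on top of the $-45$ strategy is
  decremented by $g \cdot \mathrm{PE1}_{t-1}$, skipped with a per-trial
  lapse probability. Gains $g \sim U(0.01, 0.12)$ and lapse probabilities
  $\sim U(0, 0.6)$ per participant produce incomplete, highly variable drift
  cancellation rather than a stereotyped return to zero. This is a
  phenomenological policy: the source reports *that* corrections occur and
  that they are highly variable, not their functional form.
* **Washout rotation.** Whether the rotation stays on during washout is not
  stated in the design; it is a config flag (`washout_rotation`), default
  off, which yields an after-effect $-\hat{p}$ decaying to zero.
* **Matched noise streams.** The rotation-noise stream and the $(a, b)$
  draws are keyed by the participant's index *within* condition, not by
  condition. Matched participants therefore experience identical
  perturbation sequences, and — because the update is blind to $S_t$ — their
  latent $\hat{p}$ trajectories coincide across all four conditions. This is
  the model's headline claim made structurally testable; it holds to
  floating-point cancellation error (~1e-14), since the SPE is computed as
  $c_t - \hat{h}_t$ with condition-specific $u_t$.
* **Trajectories.** Each trial's 2-D path is a near-straight ray sampled at
  0.5 cm radial steps with 0.05 cm isotropic positional jitter, purely so
  the analysis exercises the circle-crossing interpolation. The jitter is
  recording noise at the analysis boundary: it perturbs the *recorded*
  crossing angle (by about half a degree) but does not enter the SPE, which
  operates on the efference copy.

The analyzed angular error is the angle between the main target and the
point where the movement crossed the target circle *on the screen* — the
cursor, which is what the experiment displays and records. On trials without
rotation this coincides with the hand's shooting angle.

What the generator does **not** emulate: reaction and movement times (and
the 50–300 ms duration gate), online corrections within a movement, return
movements, changes of strategy use over time, and any reward-like process.
Passing tests on this cohort therefore show that the pipeline recovers the
properties of *this* generative model at the study's scale and noise — not
that the model is the true account of any particular human dataset.

## The analysis pipeline

* `shooting_angle()` interpolates the circle crossing between the last
  sample inside and the first outside the 5.3 cm circle (analytic
  segment–circle intersection).
* `block_summary()` computes each participant's mean signed error over the
  middle 10 and last 10 adaptation trials and first 10 washout trials. The
  middle-10 window of a length-$L$ block is defined as within-block trials
  $\lfloor L/2\rfloor - 4 \ldots \lfloor L/2\rfloor + 5$ (trials 95–104 for
  $L = 198$).
* `fit_exponential()` fits $Err(t) = A e^{-t/\tau}$ with $t = 0$ at the
  first trial of the fitted block, so $A$ is the initial amplitude (signed).
  Adaptation-phase fits are performed for all conditions and reported with
  their $R^2$, with no special handling. On synthetic cohorts these $R^2$
  are poor everywhere and *negative* in conditions 2/4: there the drift
  grows away from zero toward its asymptote, a shape a decay-to-zero
  exponential cannot represent, so the fit degenerates to a near-constant
  (τ pinned at the search ceiling). The human data reportedly showed the
  reverse ordering — the analysts' exact series construction for the
  adaptation fit is not recoverable, and adaptation $R^2$ is not a
  reproduction target. The
  amplitude is profiled out — for fixed $\tau$ the optimal $A$ is
  closed-form — reducing the fit to a deterministic 1-D search over $\tau$
  (80-point log grid on $\tau \in [0.1, 50L]$, then local refinement). This
  is more robust than a multi-start 2-D descent and fast enough for
  $10^4$-resample bootstraps; an all-zero series is flagged with undefined
  $\tau$. Adaptation fits start at the first strategy trial (the two
  pre-strategy rotation trials are a separate block).
* `bootstrap_fit()` draws participants with replacement (default 10000
  resamples), refits the resample-mean series, and reports percentile 95%
  intervals — "confidence interval" is otherwise unspecified in the
  procedure being mirrored, and percentile intervals are the simplest
  defensible reading.
* `condition_anova()` and `adaptation_washout_correlation()` are standard
  one-way ANOVA + Tukey HSD and per-condition Pearson correlations on the
  window means; no multiple-testing correction beyond Tukey is applied.

```{r washout-fit}
fit <- fit_exponential(-20 * exp(-(0:79) / 28) )
fit
```

## Reproducible orchestration

`run_simulate()` / `run_analyze()` / `run_report()` chain the pipeline and
write tidy CSVs plus a JSON manifest (seed, full config, config hash, md5 of
every output); a fixed seed and config reproduce every file byte for byte.
The numbered scripts under `analysis/` drive them in order. Configuration
can be supplied as a flat YAML file via `read_config()`, which rejects
unknown keys. One master seed is split into per-participant child streams,
all below $2^{31}$.

## Problem sizes and what the tests assert

The test suite runs the full model and pipeline at the study's own scale
where the claim depends on it, and at reduced scale elsewhere (shortened
blocks, 2–3 participants per condition, 50–500 bootstrap resamples) to keep
the suite fast. The scale choices we consider meaningful:

* parameter recovery uses 50 replicate 13-participant cohorts with known
  $(a, b) = (0.98, 0.018)$, default noise, zero correction gains and
  trajectories disabled (their half-degree jitter is irrelevant to the
  latent dynamics); $a - b$ inverted from the fitted washout $\tau$ is
  required within 10% in every replicate;
* the qualitative drift/washout dissociation is asserted over three
  replicate default cohorts (consecutive seeds): smaller end-of-adaptation
  drift with PE1 than without in every cohort, overlapping washout $A$ and
  $\tau$ bootstrap CIs (10000 resamples) across all four conditions in the
  majority of cohorts, and a positive end-drift ↔ after-effect association
  in conditions 2 and 4 as a one-sided test on the pooled participants. The
  replicate-level framing reflects that each such pattern is itself a
  stochastic outcome of a 13-participant cohort: with identical latent
  dynamics across conditions, one pair of 95% intervals can still miss by
  sampling alone, and a single cohort's correlation test at $n = 13$ is
  underpowered for the modest true association this generator produces
  (participants with larger $b$ drift further but also wash out faster,
  which compresses the after-effect spread).

## Known limitations

* The single-state model cannot express fast/slow memory dissociations; the
  no-feedback block simply applies 10 steps of retention. Questions about
  differential decay of memory components are outside its scope.
* The correction policy is one plausible mechanism; real corrective behavior
  may be lumpier (strategy re-aiming in discrete steps) or anticipatory.
* Baseline and familiarization trials use the same motor-noise SD; no
  learning-to-baseline or fatigue effects are modeled.
* $R^2$ values, $F$ statistics and $p$-values from the original human data
  are not reproduction targets — the raw data are not available — and
  nothing in this package should be read as estimating them.
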