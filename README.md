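# vmradapt

Simulation and analysis of *implicit drift* in visuomotor rotation
adaptation: a trial-by-trial state-space model driven by sensory prediction
errors (SPEs), a seeded synthetic cohort generator for a four-condition
target-removal shooting experiment, and the statistical pipeline used to
analyze it.

## The problem

In a classic paradigm, cursor feedback of a fast shooting movement is
rotated 45° counter-clockwise and participants are told to cancel it by
aiming at a neighboring target 45° clockwise. The explicit strategy works
immediately — the task error starts near zero — yet the cursor then drifts
clockwise away from the target, and strong after-effects appear once the
strategy is dropped. The drift is the fingerprint of an implicit learning
process that keeps updating an internal model from the SPE, the mismatch
between observed and predicted cursor position, regardless of task success.
Removing the main target, the neighboring target, both, or neither after
movement onset (conditions 3 / 2 / 4 / 1 of a 2×2 design) dissociates which
error signals can influence behavior.

The package is for computational motor-control researchers who want to
regenerate, probe, or extend that result pattern without access to human
data: every analysis runs end-to-end on synthetic cohorts.

## The model

With angles in degrees (CCW-positive, main target at 0), trial *t* obeys

    u_t   = -p̂_t + S_t + n^u_t          motor command
    c_t   =  u_t + p_t + n^p_t           cursor feedback
    ĥ_t   =  u_t + p̂_t                  forward-model prediction
    ε_t   =  c_t − ĥ_t = p_t + n^p_t − p̂_t     SPE
    p̂_t+1 =  a·p̂_t + b·ε_t              memory update

with retention rate *a*, learning rate *b*, motor noise SD σ_u and
perturbation noise SD σ_p. The motor command cancels out of the SPE, so the
memory update is blind to the strategy, to corrections, and to target
visibility — the property the experiment tests behaviorally. Two analytic
consequences anchor the test suite: the noise-free drift converges to the
full rotation magnitude when *a* = 1, and the washout error decays as
(a−b)^t, so a fitted exponential time constant satisfies τ = −1/ln(a−b).

## Worked example

Simulate the default cohort (4 conditions × 13 participants, full block
schedule 110/40/2/198/10/80, σ_u = 6.1°, σ_r = 0.5°), summarize the block
windows, and bootstrap the washout fit for condition 4:

```r
library(vmradapt)
library(dplyr)

tab <- add_errors(simulate_cohort(n_per_condition = 13, default_config(), seed = 1))
summaries <- block_summary(tab)
summaries |> group_by(condition) |>
  summarise(adapt_last10 = mean(adapt_last10),
            washout_first10 = mean(washout_first10))
#> # A tibble: 4 × 3
#>   condition adapt_last10 washout_first10
#>       <int>        <dbl>           <dbl>
#> 1         1       -1.56            -13.4
#> 2         2      -19.8             -13.1
#> 3         3       -0.305           -14.5
#> 4         4      -19.3             -12.6

bootstrap_fit(filter(tab, condition == 4), block = "washout",
              n_resamples = 10000, seed = 2)
#> participant bootstrap (10000 resamples, block = washout)
#>   A    -14.649  [-16.227, -13.037]
#>   tau   29.822  [27.561, 32.851]
#>   r2     0.796  [0.597, 0.773]
```

Read it as the experiment's dissociation: where the cursor-to-main-target
error (PE1) stayed visible (conditions 1 and 3), corrective behavior pulls
the late-adaptation error back toward 0°; where it was hidden (2 and 4) the
drift runs on to about −20°. Yet the washout after-effect is ≈ −13° in all
four conditions — the implicit memory, updated by SPEs alone, does not care
— and its decay amplitude *A* and time constant τ (in trials) carry
overlapping bootstrap confidence intervals across conditions.

The numbered scripts under `analysis/` run the same pipeline as a workflow
(`01_simulate.R` → `02_analyze.R` → `03_report.R`, plus
`04_parameter_recovery.R`), writing tidy CSVs and manifests under
`results/`.

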