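# evastream

Evidence-accumulation modelling of bistable auditory streaming.

A repeating `ABA_` tone triplet (500 ms: tone A, tone B, tone A, silent
gap) is perceived either as one galloping stream (*integration*, I) or as
two parallel streams (*segregation*, S). Listeners start near-uniformly in
integration, the probability of reporting segregation builds up over
seconds to a level that grows with the semitone separation DF of the
tones, and perception then alternates spontaneously with gamma-distributed
dominance durations. `evastream` is for computational neuroscientists and
psychophysicists who want to simulate and analyse this behaviour with a
mechanistic, neurally grounded model — and to see quantitatively why the
classical per-triplet signal-detection account fails at the single-trial
level.

## The model in brief

A feed-forward network advanced once per 500-ms triplet:

- **Input layer** — A1-like units emit Poisson spike counts with
  adapting means `m(t, DF) = m* + (m1 − m*) exp(−1.1 (t − 1))`,
  interpolated across DF by a power law fitted in log–log space.
- **Sampler layer** — `N_sl = 20` binary units each pool `N_in = 5` input
  units and vote for integration when the pooled mean count reaches
  `C_th = 4.21` spikes/triplet. The vote fractions `p_I, p_S = 1 − p_I`
  are the evidence streams; their analytic law is a Poisson CDF.
- **Accumulation layer** — two saturating accumulators
  `x(t+1) = x(t) + (T − x(t)) p(t) + σ ξ(t)`: the unit collecting evidence
  *against* the current percept saturates at a target `T_a` just below the
  decision threshold θ = 1 under noise `σ_a = 0.085`; the *for* unit sits
  at `T_f = 0.6` under `σ_f = 0.03`. A threshold crossing by the
  against-unit switches the percept and resets both units to the
  for-unit's pre-switch value. Noise-free, the system is bistable and
  never switches; alternation is noise-driven escape, which is what makes
  the simulated duration distributions gamma-like (shape ≈ 2 for first,
  ≈ 2.6 for subsequent percepts) rather than normal or exponential.

The analysis suite provides duration normalization, gamma maximum
likelihood with broom-style `tidy()`/`glance()`, parametric-bootstrap
goodness of fit, buildup functions with bootstrap confidence bands,
two-parameter `(T_a, σ_a)` response-diagram sweeps with region
classification, and the signal-detection baseline (independent per-triplet
classification, geometric run lengths, neurometric curves).

## Worked example

Simulate the equidominance condition (DF = 5 semitones, 675 trials of 60
triplets, the behavioural batch size) and summarise it:

```r
library(evastream)
library(dplyr)

ex <- run_experiment(5, n_trials = 675, seed = 42)

percept_durations(ex) |>
  group_by(label, ordinal) |>
  summarise(mu = mean(duration_s), n = n(), .groups = "drop")
#> # A tibble: 4 × 4
#>   label ordinal       mu     n
#>   <chr> <chr>      <dbl> <int>
#> 1 I     first       5.30   530
#> 2 I     subsequent  3.36  1417
#> 3 S     first       6.94   143
#> 4 S     subsequent  5.07  1528
```

Mean durations land on the behavioural values for this condition (first
integration ≈ 5.3 s, subsequent integration ≈ 3.4 s, subsequent
segregation ≈ 5.2 s). The buildup function plateaus near the behavioural
asymptote 0.6, and the normalized subsequent durations are gamma with the
behavioural shape:

```r
buildup_plateau(buildup(ex, n_boot = 0))
#> [1] 0.6142222

d <- percept_durations(ex) |>
  filter(ordinal == "subsequent") |>
  normalize_durations(by = "label")
glance(gamma_mle(d$d_tilde))
#> # A tibble: 1 × 8
#>   alpha mu_tilde    cv skewness log_lik     n p_value converged
#>   <dbl>    <dbl> <dbl>    <dbl>   <dbl> <int>   <dbl> <lgl>    
#> 1  2.52    1.000 0.630     1.26  -2389.  2945      NA TRUE
```

The signal-detection baseline, run through the same duration pipeline,
produces percept phases an order of magnitude too short:

```r
rl <- run_lengths(sdt_classify(5, n_trials = 675, seed = 3))
mean(rl$duration_s)
#> [1] 1.051063
```

`autoplot()` methods exist for buildup curves, sweeps and gamma fits. A
thin command-line wrapper with `run`, `sweep`, `sdt`, `fit-sampler` and
`stats` subcommands lives at `inst/cli/eva.R`.

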