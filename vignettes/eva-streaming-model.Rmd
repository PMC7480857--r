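---
title: "An evidence-accumulation model of bistable auditory streaming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evidence-accumulation model of bistable auditory streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evastream)
library(dplyr)
```

## The phenomenon

A repeating `ABA_` triplet of pure tones — high tone A, low tone B, high
tone A, then a silent gap, 500 ms in all — is heard either as one galloping
stream (*integration*, I) or as two parallel streams (*segregation*, S).
Perception is bistable: the first percept is usually integration, the
probability of reporting segregation builds up over seconds to a level that
grows with the tone-frequency separation DF (in semitones), and thereafter
the two percepts alternate spontaneously with dominance durations of a few
seconds whose normalized distributions are gamma-like (shape ≈ 2 for the
trial's first percept, ≈ 2.6 for subsequent ones).

`evastream` implements a stochastic network model of this process together
with the statistics used to evaluate it, and the classical per-triplet
signal-detection baseline it argues against.

## The model

The simulator is a feed-forward network of three layers, advanced once per
triplet (the model's discrete time step, 0.5 s):

1. **Input layer.** A1-like tone-A-selective units emit Poisson spike
   counts during the B tone with mean
   $m_{t,DF} = m^*_{DF} + (m_{1,DF} - m^*_{DF}) e^{-1.1(t-1)}$, an
   adaptation curve parameterized by first-triplet and asymptotic means at
   base separations DF = 1, 3, 6, 9 (`spike_mean_model()`); separations 5
   and 7 are obtained per triplet by a log–log least-squares power fit
   $m = a\,DF^b$ across the base values (`interpolate_mean()`).
2. **Sampler layer.** Each of $N_{sl} = 20$ binary units pools
   $N_{in} = 5$ input units and votes 1 (for integration) when the pooled
   mean count reaches the threshold $C_{th} = 4.21$ spikes/triplet, else 0.
   Because a pool of independent Poisson units is itself Poisson, the vote
   probability has the closed form implemented in
   `segregation_probability()`, and the vote fractions $p_I, p_S$ have
   binomial moments with variance $p(1-p)/N_{sl}$. Granularity matters: a
   small pool keeps trial-to-trial variability high enough that the
   asymptotic vote probabilities remain graded across DF = 3, 5, 7 rather
   than saturating at 0 or 1.
3. **Accumulation layer.** Two units integrate the vote fractions with
   saturating, state-dependent increments
   $x(t+1) = x(t) + (T - x(t))\,p(t) + \sigma \xi(t)$. The unit gathering
   evidence *against* the current percept targets a level $T_a$ just below
   the decision threshold $\theta = 1$ under noise $\sigma_a = 0.085$; the
   *for* unit targets $T_f = 0.6$ under weaker noise $\sigma_f = 0.03$. A
   switch occurs when the against-unit crosses $\theta$; both units then
   reset to the value the for-unit held just before the switch, and roles
   swap. With all targets sub-threshold the noise-free system is bistable —
   switching is purely noise-driven escape from an attractor, which is what
   produces gamma-like rather than normal or exponential duration
   distributions at the fitted noise level.

A trial runs 60 triplets (30 s). The accumulators sit at a common baseline
$b = 0.7$ through a latency period; at triplet $T_{Lat} = 4$ the first
percept label is drawn (Bernoulli, with the behavioural first-segregation
proportions 103/675, 137/675, 220/675 at DF = 3, 5, 7) and the dynamics
begin. Percept durations are the gaps between threshold crossings; the
final, truncated interval is excluded from statistics.

```{r quick-run}
ex <- run_experiment(5, n_trials = 120, seed = 1)
percept_durations(ex) |>
  group_by(label, ordinal) |>
  summarise(mean_s = mean(duration_s), n = n(), .groups = "drop")
```

## Parameters and where they come from

| Parameter | Default | Units | Role |
|---|---|---|---|
| `m_first`, `m_asym` | 7.25/6.25/6/5.25, 6.09/4.57/3.95/3.44 | spikes/triplet | adaptation endpoints at DF = 1/3/6/9 |
| decay rate | 1.1 | per triplet | A1 adaptation speed |
| `n_in`, `c_th` | 5, 4.21 | units, spikes/triplet | pool size and vote threshold, fit to the asymptotic buildup levels 0.45/0.6/0.65 |
| `n_sl` | 20 | units | sampler-layer size; only its reciprocal variance matters |
| `t_for`, `sigma_for` | 0.6, 0.03 | dimensionless | for-accumulator target and noise |
| `sigma_against` | 0.085 | dimensionless | against-accumulator noise, common to all conditions |
| `t_against` | per-DF table | dimensionless | against-target, tuned per percept class (first/subsequent × I/S) to the behavioural means |
| `baseline`, `threshold` | 0.7, 1 | dimensionless | latency value and decision threshold |
| `latency_triplets` | 4 (2 s) | triplets | when the first percept is identified |

Two parameters do the quantitative work: `t_against` (how near saturation
sits to threshold) and `sigma_against` (how hard noise pushes across). The
closed-form AR(1) moments (`ar1_moments()`) give the necessary switching
condition `sigma_min()` $= (1-T_a)\sqrt{1-p_M^2}/3$: below it the threshold
lies more than three stationary standard deviations above the saturation
level and alternations effectively stop.

`sweep_eva()` maps the two-parameter response diagram — no-switch region at
small noise, overlong durations at moderate noise, a matching band, then
short exponential-like durations — and `select_t_a()` implements the tuning
rule (mean within 10% of a behavioural standard error, then best shape).

## Design choices in the open

- **Latency bookkeeping.** The latency period covers the triplets strictly
  before $T_{Lat}$; the first percept is identified at $T_{Lat}$ and its
  duration is measured from there to the first crossing. The behavioural
  latency is only described as "typically 2 s", so a fixed 4-triplet
  default is used; per-trial latency distributions can be emulated by
  varying `latency_triplets` across trials.
- **Adaptation curve for all triplets.** The exponential fit is used for
  every triplet (its decay constant 1.1/triplet makes it
  indistinguishable from the asymptote after a few triplets), since only
  the fitted endpoint parameters are available.
- **Power-law interpolation in log–log space.** Ordinary least squares on
  logs is deterministic and closed-form; it reproduces the reference
  asymptotic vote probabilities, which is the only available validation.
- **Threshold conventions.** Votes use "mean ≥ threshold"; with the default
  non-integer product $N_{in} C_{th} = 21.05$ the boundary case cannot
  occur, so the Heaviside convention at 0 is unobservable. Crossings by the
  for-accumulator are disregarded by clamping it just below threshold; if
  both units would cross in one step, the against-unit therefore wins.
- **First-to-subsequent target switch.** The against-target changes from
  its first-percept to its subsequent-percept value immediately after the
  trial's first switch.
- **Seeding.** Every trial, bootstrap and sweep cell draws its own seed
  from the master seed, so any piece can be replayed in isolation and
  results do not depend on execution order.

## The statistics suite

Durations are normalized by their group mean (`normalize_durations()`;
per-subject for behavioural-format data, pooled per condition cell for
simulations, which have no subjects) and fitted by the shape/mean gamma
density via Nelder–Mead maximum likelihood from a moment start
(`gamma_mle()`, tolerance 1e-8 on the log-likelihood). The shape alone then
fixes CV $= 1/\sqrt\alpha$ and skewness $= 2/\sqrt\alpha$, so the scaling
identity skewness = 2 CV holds for every fit. Buildup curves (`buildup()`)
are trial averages of binary S-indicators with latency counted as non-S,
so they always start at zero, and carry bootstrap confidence bands; for
long stationary phases the plateau agrees with the alternating-renewal
prediction $\mu_S/(\mu_I + \mu_S)$.

Two findings about the goodness-of-fit bootstrap (`bootstrap_gof()`) are
worth stating plainly. The classical statistic — the maximized
log-likelihood, located in its parametric-bootstrap distribution — is well
calibrated under the null but has essentially no power against shape
misfit: the maximized gamma log-likelihood depends on the data only
through the sample mean and mean log, and the maximum-likelihood equations
force the fitted gamma to match both, so the observed statistic always
sits near the centre of its bootstrap distribution (p ≈ 0.5 for uniform,
bimodal and heavy-tailed alternatives alike). It is kept as the default
for fidelity to common practice; `statistic = "ks"` bootstraps the
Kolmogorov–Smirnov distance instead and does reject misfitting data. For
publication-grade tests use `n_boot = 10000`; the examples and tests use a
few hundred replicates.

## The signal-detection baseline

`sdt_classify()` implements the memoryless alternative: classify every
triplet of every trial independently as S when one pooled mean count falls
below threshold. Its trial-averaged "neurometric" curves can match the
asymptotic buildup levels, but treating triplets independently makes
percept phases run-lengths of a biased coin: `run_lengths()` durations are
geometric with means around one second — far below the behavioural 3–5 s —
and with the analytic pmf `exponential_run_pmf()`. One caveat for shape
comparisons: a continuous gamma fitted to such short *discrete* runs
(support starting at one 0.5-s triplet) has an inflated shape parameter
(≈ 1.7–3.9 over the relevant bias range, verified against exact geometric
samples), so the baseline's failure is diagnosed by its mean durations and
its geometric run-length law, not by a literal shape-near-1 criterion.
The same discreteness floor applies to the high-noise corner of the sweep
diagrams, where mean durations shrink to a few triplets; the sweep tests
therefore verify exponential-likeness there against a matched-mean
geometric oracle rather than a fixed shape cutoff.

## What the generator does and does not emulate

Simulated experiments reproduce the design of the behavioural task — 675
trials of 60 triplets per condition, first-percept proportions, latency —
but pool all trials as one "subject": there is no inter-subject
heterogeneity, no motor delay or response error, and no correlation
between successive durations (resets erase history by construction).
Passing tests therefore show that the mechanism reproduces group-level
duration statistics and buildup, not that it captures individual
differences. The behavioural-format fixture generator
(`simulate_keypress_records()`) is an alternating-renewal sampler for
exercising the key-press readers and subject-wise statistics; it is
synthetic and is not a model of any particular subject pool.

## Problem sizes and runtime conventions

The bundled tests and the acceptance script use the full behavioural batch
size (675 trials) with ten seeded replicates for stochastic quantities,
reduced trial counts (120–400) for sweep cells, and a few hundred
bootstrap replicates; these sizes keep a complete run in the order of a
minute or two on one core while leaving Monte-Carlo error well inside the
tolerances being checked. Monte-Carlo replicate counts, trial counts and
grids are all arguments, so any analysis can be scaled up.

## Limitations

- Only the printed endpoint parameters of the A1 adaptation curves are
  available, so the input layer is an idealization of the underlying
  multi-unit data; neuronal heterogeneity around the mean counts is not
  modelled (its effect on pooled means would be negligible).
- The per-class against-target table is a fit to group behaviour, not a
  mechanistic derivation; alternative parameterizations (DF-dependent
  targets with constant input) are equally consistent with the data.
- The continuous-resetting variant that would induce correlations between
  successive durations, and continuous-time diffusion approximations, are
  out of scope.
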