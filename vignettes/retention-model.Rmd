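---
title: "A renewal-process model of skill retention under intermittent use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A renewal-process model of skill retention under intermittent use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skillret)
```

## The model

`skillret` tracks a collectively held skill whose practice depends on
irregular external events. The state variable is the number of *experts*
η — group members currently able to perform the skill. Three assumptions
define the dynamics:

1. **Exponential forgetting.** Between uses the expert count decays
   continuously, η(Δt) = η^max · e^(−Δt/τ). The forgetting time τ is the
   e-folding time: after τ unused years the pool is down to a fraction
   1/e ≈ 0.37 of its maximum. Skill-retention studies of procedural-motor
   tasks (the closest analogue to sequential craft skills) are well
   described by exponential decay, which is why the package commits to a
   single-exponential law rather than a multi-phase one.
2. **Instantaneous, complete recovery.** Each use resets the pool to
   η^max. This is deliberately the most retention-friendly recovery
   assumption: any slower recovery could only make loss more likely, so
   results about widespread loss are conservative.
3. **A one-person threshold.** The skill survives as long as at least one
   expert remains (the threshold is configurable; with threshold *m* the
   formulas below replace η^max by η^max/m). Because the decay is
   deterministic given the interval, the pool drops below one expert
   exactly when an unused interval exceeds the *maximum time*

   Δt^max = τ · ln(η^max).

Intervals between uses are independent draws from N(θ, (νθ)²) conditioned
on being positive. θ is the mean use interval in years; ν is a
dimensionless variability factor scaling the standard deviation. The
horizon is L years (default 1000). Retention means no interval up to the
horizon exceeded Δt^max.

## Parameters

| parameter | meaning | units | default / reference range |
|---|---|---|---|
| θ | mean use interval | years | sweep range 1–20 |
| ν | interval variability (sd = νθ) | — | sweep range 0–2 |
| η^max | expert pool after a use | individuals | sweep range 3–60 |
| τ | forgetting time | years | sweep range 1–16 |
| L | horizon | years | 1000 |
| K | sequences per Monte-Carlo estimate | — | 111 |
| threshold | minimum experts for retention | individuals | 1 |

The sweep ranges bound the regime the model was built to explore: annual
to once-a-generation use, near-clockwork to highly erratic events, a
handful of specialists to a whole band of 60, and forgetting on the scale
of one to sixteen years. `model_params()` warns — it does not error —
outside these ranges, because they are survey bounds, not mathematical
constraints.

## Two engines

**Monte-Carlo.** `run_sequence()` draws intervals in batches of
⌈2L/θ⌉ (twice the expected interval count, which covers the horizon in all
but rare cases; the sampler appends further batches when it does not) and
terminates at the first interval exceeding Δt^max (loss) or the first
cumulative time beyond L (retention). `estimate_retention()` runs K
sequences and reports P_r = 1 − n_losses/K with the binomial standard
error √(P_r(1−P_r)/K). At the default K = 111 the standard error is at
most ≈ 0.047.

**Closed form.** The probability that one interval exceeds the maximum
time is the normal upper tail

P_d = ½ [1 − erf((Δt^max − θ) / (θν√2))],

and taking the number of intervals in the horizon as the real-valued ratio
L/θ, the probability that none of them is fatal is

P_r = (1 − P_d)^(L/θ).

This is the product form of "no interval exceeds Δt^max in L/θ independent
tries"; it also reproduces, quantitatively, the boundary positions the
Monte-Carlo engine finds (≈ 15 → ≈ 8 → ≈ 4.4 → ≈ 2.2 years as ν goes
0 → 0.32 → 0.88 → 2 at τ = 4, η^max = 43), which the alternative reading
1 − P_d^(L/θ) does not.

Two deliberate approximations live in the closed form, and
`cross_validate()` exists to quantify rather than hide them:

* P_d uses the **untruncated** normal tail, while the simulator samples
  the positive-truncated law. The discrepancy grows with ν (at ν = 2
  roughly 31% of the untruncated mass is negative) and is exposed as an
  optional `truncation_corrected` mode that divides the tail by P(X > 0).
* The interval count is fixed at L/θ, whereas the simulator's count is
  random.

`cross_validate()` flags a parameter point when the two engines disagree
by more than three binomial standard errors plus an absolute slack of
0.02 (which absorbs the two approximations above). Over random points in
the reference ranges, at least 95% of points pass; at ν = 0 both engines
are deterministic and agree exactly.

## Numerical choices

* **Positivity by rejection, not clipping.** Negative draws are redrawn,
  realising the truncated normal exactly. Clipping to zero (or taking
  absolute values) would concentrate mass at implausibly short intervals
  and bias the renewal clock. Acceptance probability is at least
  1 − Φ(−1/ν) ≥ ½, so rejection is cheap even at ν = 2.
* **Strict loss comparison.** An interval exactly equal to Δt^max leaves
  the pool exactly at the threshold and retains; loss requires a strictly
  longer gap. The tie has probability zero under continuous intervals, but
  the convention keeps the interval rule identical to the expert-count
  rule η < threshold, and the test suite checks the two rules against each
  other on shared draws.
* **Loss time convention.** A loss is stamped at *t*(last use) + Δt^max —
  the instant the pool crosses the threshold — not at the end of the fatal
  interval.
* **Continuous expert counts.** η is continuous internally (the decay law
  is); `expert_count_display()` floors to whole individuals only at
  reporting boundaries (7.36 experts ⇒ "7 people").
* **Log-space powers.** P_r is computed as exp((L/θ)·log1p(−P_d)), which
  keeps tiny P_d (down to ~10⁻¹²) from rounding to zero depletion under
  large exponents.
* **Monotonicity tolerance.** Along θ and ν the closed-form surface is
  monotone everywhere the probability is distinguishable from zero.
  Deep inside the loss region (θ > Δt^max) the surface has genuine,
  physically irrelevant non-monotonicities at magnitudes like 10⁻²⁰, so
  monotonicity assertions in the tests tolerate increases below 10⁻⁹.
* **RNG streams.** All seeded entry points use the L'Ecuyer-CMRG
  generator; each temporal sequence (and each grid cell) gets an
  independent child stream derived from the one top-level seed, so results
  are bit-reproducible and independent of evaluation order, and the
  caller's RNG state is always restored.

## Sweeps, classification and the panel tally

`sweep_grid()` evaluates P_r over a (θ, ν) grid at fixed (τ, η^max);
the default resolution for reference figures is 50 × 50, a step of ≈ 0.04
in ν, and resolution is configurable everywhere. `classify_cells()` calls
a cell *loss* when P_r < 0.5 — the symmetric choice in the absence of any
privileged probability level — and additionally counts a *transition* band
(0.05 < P_r < 0.95) where chance, rather than parameters, decides the
outcome. The transition band widens along the forgetting-time axis as ν
grows: stochasticity matters more when events are erratic.

`count_loss_majority_panels()` tallies, across the 5 × 6 grid of
(τ, η^max) ∈ {1, 2, 4, 8, 16} × {3, 6, 12, 24, 48, 60}, the panels where
loss cells outnumber retention cells. Its variability grid defaults to
ν ∈ [0.1, 2] — the range the simulation campaign actually sweeps, with 0.1
(10% of θ) as the floor for a minimally stochastic event regime — and
yields 25 of 30 loss-majority panels, stable across 25×25, 50×50 and
100×100 resolutions. One panel (τ = 8, η^max = 48) sits almost exactly at
half loss; extending the grid down to ν = 0 adds enough deterministic
retention rows to tip that single panel, giving 24. The package reports
the grid specification alongside every tally so this sensitivity is
visible.

`find_boundary()` reports, per ν row, the θ at which P_r crosses 0.5,
linearly interpolated between bracketing grid columns; rows that never
cross report `NA`, and non-monotone rows (possible under the Monte-Carlo
engine) use the first crossing and are flagged.

## Estimating the forgetting time

`fit_forgetting_time()` fits r(t) = A·e^(−t/τ) to (time since practice,
retention fraction) data by Levenberg–Marquardt nonlinear least squares on
the original scale, initialised from a log-linear regression. Fitting on
the original scale keeps noisy observations near zero retention — whose
logs would have enormous leverage — from dominating. A is fixed at 1
(full retention at zero elapsed time) unless `fit_amplitude = TRUE`; both
unweighted fitting and the amplitude option are exposed because published
decay tables differ in whether they are normalised. Data whose log-linear
slope is non-negative (constant or improving retention) are rejected as
non-identifiable rather than returned with a meaningless τ. Confidence
intervals come from a seeded case-resampling bootstrap (default 1000
replicates, percentile interval); the point estimate never depends on the
bootstrap.

`generate_decay_data()` produces synthetic datasets — exponential decay
plus additive Gaussian noise, clamped into (0, 1] — for parameter-recovery
testing. It emulates the *structure* of published skill-retention tables
(a handful of time points, fractional retention, modest noise), not their
sampling designs: real studies have heteroscedastic, often binomial error,
unevenly spaced retest times, and between-subject variation. Passing
recovery tests therefore demonstrates that the estimator is consistent and
well-behaved on clean exponential signals, not that any particular
published τ is correct.

## Problem sizes in the test suite

The suite runs entirely on synthetic data generated at test time: grids up
to 100 × 100 cells (analytical), Monte-Carlo estimates at the default
K = 111, a 50-point engine cross-validation, and 200-replicate parameter
recovery at 20 points per dataset with noise sd 0.05 — sizes chosen so the
whole suite exercises every code path in seconds while keeping stochastic
tolerances honest (3–4 standard errors wherever an estimate is compared to
a target).

## Limitations

* Experts are lost only to forgetting; death, migration and
  between-group exchange of knowledge are outside the model.
* How non-experts acquire the skill is not modelled — recovery counts
  heads, not transmission.
* The interval law is committed to the (truncated) normal family; heavy
  tails or clustered event regimes are not represented.
* The closed form is an approximation (untruncated tail, fixed interval
  count); use the cross-validation report, not faith, where ν is large.
* Single-exponential forgetting is an idealisation of group-level memory;
  the fitting module will happily put a τ on data that a richer decay
  model would describe better, so inspect residuals.
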