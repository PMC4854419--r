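---
title: "Circuit models of intermittent rivalry and rivalry memory: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit models of intermittent rivalry and rivalry memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalrymem)
```

## The model

`rivalrymem` simulates and analyses the canonical cortical circuit for
perceptual rivalry: `N` pools of neurons coupled by mutual inhibition, each
subject to slow fatigue. With time rescaled so the activity time constant is
one, pool `i` obeys

$$\dot u_i = -u_i + f\Big(S_i + \sum_j s_{ij}\beta_{ij}u_j - \gamma a_i\Big),
\qquad \tau_a \dot a_i = -a_i + u_i, \qquad
\tau_s \dot s_{ij} = 1 - s_{ij} - \phi\, s_{ij} u_j.$$

Here `f` is a threshold gain (square root of the positive part), `beta` is a
signed weight matrix, `a_i` is *local fatigue* — subtractive negative
feedback standing for spike-frequency adaptation or within-pool synaptic
depression — and `s_ij` is *nonlocal fatigue*, an activity-dependent
depression of the synapse from pool `j`. The `s` dynamics apply uniformly to
every connection (excitatory ones included); `phi = 0` switches nonlocal
fatigue off globally. Fatigue time constants are seconds; the activity time
constant is tens of milliseconds, and results do not depend on its exact
value provided it stays much faster than the fatigue — we expose it as
`ms_per_tau` (default 5 ms in the calibrated profiles) purely to convert
between stimulus clock time and model time.

Two circuits are built in. The *quartet* circuit has four pools, `V+`, `V-`,
`H+`, `H-`, for the two orientations and rotation directions of the
ambiguous-quartet apparent-motion stimulus: competing interpretations of the
same frame transition (`V+`/`H-` and `V-`/`H+`) inhibit one another, while
like-orientation and like-direction pairs are weakly excitatory, biasing the
circuit toward orientation persistence with direction oscillating every
frame. The *reduced two-pool* circuit averages over the fast direction
oscillation, leaving mutually inhibiting `H` and `V` orientation pools;
like-orientation excitation is absorbed into the pool (or can be restored as
explicit self-excitation for the persistent-activity regime).

The percept is read off as the most active pool at a decision time.

## Stimulus protocols

Intermittent stimulation is a train of square input pulses: a
change-detecting stage turns each frame transition (every `T_frame` ms) into
a brief pulse of amplitude `S_on` to the transition-consistent pools. Between
pulses every pool receives the nonspecific background `S_off` — fixed,
zero, or zero-mean gaussian noise redrawn each integrator step (the
threshold gain rectifies such noise into an effective positive background).
Background is additive during pulses as well: a nonspecific input does not
gate off during stimulation, and it is negligible against `S_on`.

**Pulse width.** When no width is given, protocols default to a quarter of
the frame interval. The calibrated profiles instead fix the width at 20 ms
independent of `T_frame`, treating the change-detector transient as a
physiological constant. This matters: if the pulse scaled with `T_frame`,
the duty cycle — and with it the time-averaged fatigue dynamics — would be
independent of the frame interval, and the dominance duration measured in
frames would *fall* as `T_frame` grows. A fixed brief transient is both the
more physiological reading and the one under which dynamic L4 (dominance
duration in frames increasing with `T_frame`) emerges robustly.

**Symmetry breaking.** The integrator is deterministic, and a perfectly
rested circuit under symmetric drive stays symmetric forever. A tiny
activity kick (`kicked_state()`, default `1e-3` on one pool) stands in for
the fluctuation that selects the first percept; downstream results are
insensitive to its size over several orders of magnitude (checked from
`1e-4` to `1e-2`).

## Numerical scheme

Integration is fixed-step classical Runge-Kutta (RK4), compiled, with
default step `dt = tau_u / 20`; steps above `tau_u / 10` are refused. The
system is non-stiff at this time-scale separation, and a fixed step makes
runs exactly reproducible. The hard-threshold gain is continuous, so the
scheme integrates through the kink without event detection; halving the
step changes smooth endpoints by less than `1e-6`. Gaussian background is
drawn once per step from R's seeded RNG stream and held constant within the
step (the noise is white at the step scale; its effect therefore depends
mildly on `dt`, which is documented behaviour). Non-finite states abort with
a diagnostic. Decision-time states are stored exactly (probes at pulse
ends), not interpolated.

Percepts are scored at the *end* of each pulse window, where the
winner-take-all contest has had the pulse's full duration to resolve and the
imbalance is largest; the scoring phase is configurable (pulse midpoint) and
this choice is ours — nothing in the phenomena pins the exact phase.
Ties retain the previous label (perceptual hysteresis); an initial tie goes
to the lowest pool index; all-zero activity yields the label `"none"`,
excluded from durations.

## The calibrated profiles

Exact parameter values are not determined by the qualitative phenomena, so
the package ships one calibrated set per regime (`rivalry_profile()`),
chosen once by regime search and then frozen:

* **`two-pool-memory`** (local fatigue): inhibition 3, `gamma = 1.2`,
  `tau_a = 3` s, `S_on = 1`, `S_off = 0.12`, 20 ms pulses. The release
  margin works out as follows: in the off-state the dominant pool settles
  toward `u* = f(S_off - gamma u*)`, which sits below the release threshold
  `gamma a = S_off` by `u*^2` — a few per-pulse fatigue increments. Pulses
  push fatigue over the threshold after a number of frames that grows with
  the frame interval (more relaxation between pulses), giving dynamic L4
  across 150-550 ms and no alternation beyond ~700 ms; at `S_off = 0` the
  percept alternates every pulse; the off-state asymmetric state persists
  indefinitely (it exists at arbitrarily low background whenever
  `beta f(S) > S > 0`, which concavity propagates from `S_on` down); and
  from rest at `T_frame = 105` ms the epochs habituate
  (11, 10, 5, 3, 2, ... frames).
* **`two-pool-nonlocal`** (`phi = 3`, `tau_s = 3` s): switches are escapes —
  depression of the dominant pool's outgoing inhibition lets the suppressed
  pool break through — and from rest the *first* epoch is the shortest,
  the mirror image of habituation, because the rested challenger has the
  shortest distance to the critical inhibition ratio.
* **`quartet-memory`**: the four-pool analogue (like-orientation 0.4,
  like-direction 0.1) producing direction oscillation within a persisting
  orientation and slower orientation rivalry.
* **`spiking`**: see below.

The same two-pool circuit passes through the full static-drive bifurcation
sequence: symmetric rest for `S < 0`, a pitchfork at `S = 0` into
winner-take-all, a limit-cycle (static rivalry) window around `S ≈ 6-9`
opening on a saddle-node-on-limit-cycle and closing through a small
bistable window, then a symmetric active state. The pulsed protocols use an
on-state in the winner-take-all region — intermittent rivalry does not
require the static limit cycle, only off-state asymmetry.

Switches are classified by the two existence clauses of the asymmetric
state, `s_1\beta f(S_{on}-\gamma a_1) + \gamma a_2 > S_{on}` (inhibition
strong enough to suppress the loser) and `S_{off} > \gamma a_1` (fatigue low
enough for the winner to stay active on background): a *release* is a
failure of the second, an *escape* of the first. Both clauses are evaluated
over the window between the last two decisions, because the actual flip
happens between pulses; when pulsed dynamics let the challenger win the
on-state race slightly before the quasi-static inhibition clause fails, the
transfer is still classified as an escape provided the winner's off-state
memory was intact.

## Fixed points and regime scans

`find_fixed_points()` enumerates the possible active sets of the two-pool
circuit with the slow variables at their drive-consistent equilibria
(`a_i = u_i`, `s_ij = 1/(1 + phi u_j)`): the empty and single-pool supports
and the symmetric diagonal are solved by bracketed one-dimensional root
finding on a 400-point grid, and both-active asymmetric states by a damped
Newton pass from an 8 x 8 lattice of starts. Solutions are kept when the
residual is below `1e-10` and inactive pools have non-positive gain
arguments. Stability comes from the eigenvalues of the full
`(u, a, s)` Jacobian by central differences; a state lying exactly on the
gain kink is reported `"marginal"` rather than misclassified (the hard gain
has no two-sided derivative there, and its one-sided slope diverges).
Limit cycles are detected by simulation — 10 `tau_a` of transient, then a
window (default 50 `tau_a`) in which at least four dominance switches with
period coefficient-of-variation under 10% must occur. Every stable fixed
point is cross-checked against long integrations from seeded random starts
(agreement to `1e-6` in `u`, both directions).

Sign conventions: circuits store signed `beta_ij`; the existence-condition
helpers take the inhibition *magnitude*, and the adapters assert the
off-diagonal sign. Fatigue arguments to `asymmetric_condition()` are passed
pre-scaled by `gamma`, since the condition is written in effective input
units.

## The spiking counterpart

`spiking_circuit()` is a deliberately minimal conductance-style analogue:
two pools of leaky integrate-and-fire neurons (rest 0, threshold 1,
`tau_m = 10` ms, 2 ms refractory), a calcium-like adaptation current
incremented per spike and decaying over seconds (the local fatigue), and
cross-pool inhibitory synapses with optional short-term depression (the
nonlocal fatigue). Pools are small (20 neurons by default) for speed, so
dominance statistics carry strong finite-size noise. Background is a
below-rheobase constant current (0.92) plus white current noise; the
off-state memory is noise-driven low-rate firing of the winner, which keeps
the loser suppressed. The calibrated spiking profile disables depression
(local fatigue only) and shows dynamic L4 over 250-500 ms in the large
majority of seeds, with a no-alternation region beyond.

Two honest caveats. First, run-to-run variance of mean dominance duration
is not a clean finite-size observable here because the *mean* itself grows
with pool size (larger pools fluctuate less and hence switch more rarely);
the finite-size property is instead verified on the off-state pool-rate
estimate, whose across-seed variance drops about 25-fold from 8 to 32
neurons per pool while its mean stays consistent with the rate picture.
Second, rested-start habituation (first epoch longest) appears only in a
minority of seeds under this neuron model: with stochastic switching the
epoch boundary is an adaptation-gap race that structurally favours a short
first epoch. The rate model reproduces habituation robustly; the spiking
window for it is evidently much narrower, and we report the observed
fraction (via the `spiking` recipe) rather than assert it.

## Dominance-duration survival analysis

Percept reports are converted to dominance records: inter-report intervals
in movie frames (`duration / T_frame`, rounded to the nearest frame,
floored at one), the within-block order as the percept epoch, and the
interval from the last report to block end as a right-censored record —
the percept outlived the block, so its duration is a lower bound. Blocks
with fewer than two reported switches are dropped and subjects left with no
adequate block are removed, with an exclusion report. Percept types are
pooled; the label is not a covariate.

The fit is a Cox proportional-hazards partial likelihood with a
subject-level gamma frailty (random effect), delegated to
`survival::coxph()` with a `frailty()` term; the package implements the
bespoke parts around it. Because the frailty machinery has no residual
test, the proportionality check extracts the noise vector
`z = lp - theta x` (the linear predictor minus the fixed effect, i.e. the
random-effect contribution), refits a plain `coxph` with `z` as an offset,
and tests the scaled Schoenfeld residual slope over time with `cox.zph`;
slope `p > 0.05` supports proportionality.

The synthetic report generator emulates the study design — by default 16
subjects, four test blocks at 300/350/400/450 ms lasting 5/5/6/8 minutes —
with per-subject gamma frailty and log-hazard slopes on the frame interval
and the epoch. One structural point: a strictly log-linear *positive* epoch
effect cannot fill arbitrarily long blocks (expected block time under a
geometric hazard increase is a convergent series), so by default the epoch
effect saturates at epoch 12, which is also the phenomenologically sensible
reading of habituation levelling off. Parameter-recovery simulations
therefore use `epoch_cap = Inf` with two-minute blocks, where generator and
fit share the exactly linear form; they also inject one nonzero effect at a
time, since hazard ratios are not collapsible over omitted covariates — a
two-effect generator biases single-covariate fits away from zero even in
large samples. Under that design the fit recovers the generator coefficient
within two standard errors in well over 90% of seeded replicates, the Wald
p-value is uniform under the null (KS check), and the proportionality
p-value exceeds 0.05 in ~95% of proportional-hazards datasets while
detecting a mid-duration effect reversal with high power.

What the generator does *not* emulate: reaction-time lag between neural
switch and key press, learning across blocks, or any percept-type
structure. Passing recovery on it validates the analysis pipeline, not the
experiment.

## Problem sizes

Default analysis sizes were chosen to keep every bundled experiment at
desk scale: dynamic-L4 sweeps use 150 frame transitions per interval;
habituation runs 120 transitions; oracle cross-checks use 100 random
initial conditions; recovery uses 8 subjects x 4 two-minute blocks per
replicate with 40-50 replicates per covariate; spiking sweeps use 150
frames x 10 seeds. All are ordinary laptop workloads.

## Known limitations

* The calibrated profiles reproduce regimes, not any particular published
  curve; the quantitative boundaries (e.g. the ~700 ms alternation limit)
  are properties of this parameter set.
* The bifurcation scan labels regimes from fixed points plus
  simulation-detected cycles; it does not continue periodic orbits or
  compute normal forms, so Hopf sub/supercriticality is inferred only from
  the coexistence pattern.
* Gaussian background is white per integrator step, not an
  Ornstein-Uhlenbeck process; its rectified mean depends on `dt`.
* The spiking model is a minimal analogue, not a biophysically detailed
  conductance model; see the caveats above.
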