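# rivalrymem

Mutual-inhibition circuit models of perceptual rivalry, intermittent
rivalry, and rivalry memory — with the dominance-duration survival analysis
to go with them.

When an ambiguous stimulus such as the quartet apparent-motion illusion is
presented *intermittently*, the percept that dominated before a blank tends
to return after it (rivalry memory), dominance durations measured in movie
frames grow with the frame interval (a dynamic form of Levelt's fourth
proposition), and the first percepts after rest last longest, shortening to
a steady state (habituation). `rivalrymem` implements the canonical
cortical circuit that accounts for all of this with one ingredient beyond
mutual inhibition and fatigue: a small nonspecific background input that
lets the winner's activity survive the off-state at an arbitrarily low
level. It is aimed at computational neuroscientists studying rivalry and
at psychophysicists who want a generative model and a matching statistical
pipeline for percept-report data.

## The model

Pool activities follow a threshold-gain rate model (time rescaled so the
activity time constant is 1):

    du_i/dt  = -u_i + f( S_i + sum_j s_ij beta_ij u_j - gamma a_i )
    tau_a da_i/dt  = -a_i + u_i                  (local fatigue)
    tau_s ds_ij/dt = 1 - s_ij - phi s_ij u_j     (nonlocal fatigue)

with `f(x) = sqrt(max(x, 0))`. The quartet circuit uses four pools (`V+`,
`V-`, `H+`, `H-`); the reduced circuit averages out the fast direction
oscillation into two orientation pools. The asymmetric one-winner state
exists whenever `s1 * beta * f(S - a1) + a2 > S > a1`; for a concave gain,
truth at the on-state input implies truth at every lower background level —
that inequality *is* the memory mechanism. The package adds fixed-point and
bifurcation analysis (pitchfork at `S = 0`, SNIC onto the static-rivalry
limit cycle), a spiking two-pool counterpart, percept readout into
dominance records, and a mixed-effects Cox survival stage with right
censoring, subject screening, and a Schoenfeld-residual proportionality
check.

## Worked example

Simulate the calibrated two-pool memory regime under 105 ms intermittent
stimulation, score dominance epochs, sweep the frame interval, and fit the
survival model to a synthetic report dataset:

```r
library(rivalrymem)
pr <- rivalry_profile("two-pool-memory")
proto <- profile_protocol(pr, T_frame_ms = 105, n_frames = 120)
traj <- simulate(pr$circuit, protocol = proto,
                 state0 = kicked_state(pr$circuit))
head(dominance_records(dominant_labels(traj)), 5)
#>   epoch label T_D censored
#> 1     1     H  11    FALSE
#> 2     2     V  10    FALSE
#> 3     3     H   5    FALSE
#> 4     4     V   3    FALSE
#> 5     5     H   2    FALSE
```

The first epoch (11 frames) outlasts the second (10), shortening toward a
steady state: habituation from rest. Dominance duration versus frame
interval shows dynamic L4 and the alternation boundary:

```r
sweep_dynamic_L4(pr$circuit, c(150, 250, 350, 450, 550, 700),
                 pulse_spec(pr$S_on, width_ms = pr$pulse_width_ms),
                 background_spec("fixed", S_off = pr$S_off),
                 horizon_frames = 150, state0 = kicked_state(pr$circuit))
#>   T_frame_ms   mean_TD n_switches no_alternation
#> 1        150  3.340909         44          FALSE
#> 2        250  4.257143         35          FALSE
#> 3        350  5.103448         29          FALSE
#> 4        450  6.041667         24          FALSE
#> 5        550 11.500000         12          FALSE
#> 6        700        NA          0           TRUE
```

Mean dominance rises from 3.3 to 11.5 frames across the grid; beyond
~700 ms the last percept never alternates within the horizon — fatigue
decays between pulses faster than it accumulates. The survival stage on a
synthetic percept-report session (the generator embeds a true hazard ratio
of 0.996 per ms of frame interval):

```r
ds <- synth_reports(n_subjects = 16, seed = 1)
fit <- fit_cox_mixed(screen_subjects(records_from_reports(ds)),
                     fixed = "T_frame")
fit
#> mixed-effects Cox fit of dominance duration on T_frame
#>   hazard ratio 0.9960 (coef -0.00400, s.e. 0.00039), Wald p = 1.19e-24
#>   2219 samples, 2155 events; frailty variance 0.5505
proportionality_check(fit)
#>         x    GLOBAL
#> 0.1181169 0.1181169
```

The hazard ratio below 1 means longer dominance at longer frame intervals;
the residual-slope p above 0.05 supports the proportional-hazards
assumption. See `vignettes/rivalry-circuit-methods.Rmd` for the model
assumptions, calibrated parameter sets, and every numerical design choice.

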