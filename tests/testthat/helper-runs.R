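# shared fixtures: profile runs used by several test files

memory_profile <- rivalry_profile("two-pool-memory")
nonlocal_profile <- rivalry_profile("two-pool-nonlocal")

# simulate a profile's intermittent protocol from a kicked rested state
run_profile <- function(profile, T_frame_ms = profile$T_frame_ms,
                        n_frames = 60, background = "fixed", ...) {
  proto <- profile_protocol(profile, T_frame_ms = T_frame_ms,
                            n_frames = n_frames, background = background)
  simulate(profile$circuit, protocol = proto,
           state0 = kicked_state(profile$circuit, profile$kick_pool,
                                 profile$kick_eps), ...)
}

epoch_lengths <- function(traj) {
  rec <- dominance_records(dominant_labels(traj))
  rec$T_D[!rec$censored]
}

# assert CircuitState invariants along a whole trajectory
expect_state_invariants <- function(traj) {
  expect_true(all(traj$u >= 0))
  expect_true(all(traj$a >= 0))
  expect_true(all(traj$s > 0 & traj$s <= 1 + 1e-12))
  expect_true(all(diff(traj$times_ms) > 0))
}
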