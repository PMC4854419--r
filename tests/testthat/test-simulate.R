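test_that("constant drive relaxes to the gain value with the activity time constant", {
  # uncoupled pools, no fatigue: du/dt = -u + f(S), so
  # u(t) = f(S) (1 - exp(-t)) in rescaled time
  circ <- rivalry_circuit(matrix(0, 2, 2), ms_per_tau = 10)
  tr <- simulate(circ, drive = c(4, 0.25), t_end_ms = 80, dt = 0.05)
  t_int <- tr$times_ms / 10
  for (j in 1:2) {
    expected <- gain_eval(circ$gain, c(4, 0.25)[j]) * (1 - exp(-t_int))
    expect_lt(max(abs(tr$u[, j] - expected)), 1e-5)
  }
})

test_that("sub-threshold constant drive keeps the circuit at rest", {
  circ <- two_pool_circuit(inhibition = 2, local_fatigue = 1)
  tr <- simulate(circ, drive = c(-0.5, -0.5), t_end_ms = 500)
  expect_true(all(tr$u == 0))
  expect_true(all(tr$a == 0))
})

test_that("too-large steps are refused and divergence is diagnosed", {
  circ <- two_pool_circuit()
  expect_error(simulate(circ, drive = c(0, 0), t_end_ms = 10, dt = 0.2),
               "dt")
})

test_that("halving the step leaves smooth endpoints unchanged within tolerance", {
  circ <- two_pool_circuit(inhibition = 2, local_fatigue = 1.2,
                           tau_a_ms = 2000, ms_per_tau = 5)
  st <- kicked_state(circ, eps = 0.05)
  end_u <- lapply(c(0.05, 0.025), function(dt)
    final_state(simulate(circ, drive = c(0.5, 0.5), t_end_ms = 2000,
                         state0 = st, dt = dt))$u)
  expect_lt(max(abs(end_u[[1]] - end_u[[2]])), 1e-6)
})

test_that("trajectories preserve the state invariants", {
  pr <- memory_profile
  for (Tf in c(105, 350)) {
    tr <- run_profile(pr, T_frame_ms = Tf, n_frames = 40)
    expect_state_invariants(tr)
  }
  trn <- run_profile(nonlocal_profile, n_frames = 40)
  expect_state_invariants(trn)
  expect_true(any(trn$s < 1)) # nonlocal fatigue actually engages
})

test_that("gaussian background runs are reproducible bit for bit by seed", {
  circ <- memory_profile$circuit
  proto <- profile_protocol(memory_profile, n_frames = 10,
                            background = "gaussian", sigma = 0.05, seed = 11)
  t1 <- simulate(circ, protocol = proto, state0 = kicked_state(circ))
  t2 <- simulate(circ, protocol = proto, state0 = kicked_state(circ))
  expect_identical(t1$u, t2$u)
  t3 <- simulate(circ, protocol = proto, state0 = kicked_state(circ),
                 seed = 12)
  expect_false(identical(t1$u, t3$u))
})

test_that("quartet trajectories are equivariant under the symmetry group", {
  circ <- quartet_circuit(inhibition = 3, like_orientation = 0.4,
                          like_direction = 0.1, local_fatigue = 1.2,
                          tau_a_ms = 3000, ms_per_tau = 5)
  # swap H <-> V orientations: permutation of pool indices
  perm <- match(c("H+", "H-", "V+", "V-"), circ$pool_labels)
  st <- rested_state(circ); st$u[1] <- 1e-3
  st_p <- rested_state(circ); st_p$u[perm[1]] <- 0 # placeholder
  st_p$u <- st$u[perm]
  drive_fn <- function(t_ms) c(0.3, 0.1, 0.05, 0.2)
  drive_fn_p <- function(t_ms) drive_fn(t_ms)[perm]
  tr <- simulate(circ, drive = drive_fn, t_end_ms = 400, state0 = st)
  tr_p <- simulate(circ, drive = drive_fn_p, t_end_ms = 400, state0 = st_p)
  expect_equal(tr_p$u, tr$u[, perm], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("asymmetric state persists indefinitely at very low background", {
  # strong mutual inhibition, no fatigue: after an asymmetric on-state the
  # sign of u1 - u2 never changes on S_off = 0.001, however long the run
  circ <- two_pool_circuit(inhibition = 2, ms_per_tau = 10)
  on <- simulate(circ, drive = c(1, 1), t_end_ms = 500,
                 state0 = kicked_state(circ))
  st <- final_state(on)
  expect_gt(st$u[1] - st$u[2], 0.5) # winner-take-all resolved
  off <- simulate(circ, drive = c(0.001, 0.001), t_end_ms = 2e5, state0 = st)
  d <- off$u[, 1] - off$u[, 2]
  expect_true(all(d > 0))
  expect_equal(unname(off$u[nrow(off$u), 1]), gain_eval(circ$gain, 0.001),
               tolerance = 1e-6)
})

test_that("reciprocal excitation in the critical window gives persistent activity", {
  # bistability: a brief input leaves the pool in an elevated state with no
  # drive; a hard reset to zero stays at zero
  circ <- two_pool_circuit(inhibition = 3, self_excitation = 2.5,
                           local_fatigue = 1.2, tau_a_ms = 3000,
                           ms_per_tau = 5)
  pulse_fn <- function(t_ms) if (t_ms < 50) c(1, 0) else c(0, 0)
  tr <- simulate(circ, drive = pulse_fn, t_end_ms = 30000)
  u_end <- final_state(tr)$u
  # persistent level solves u = f((w_self - gamma) u) => u = w_self - gamma
  expect_equal(u_end[1], 2.5 - 1.2, tolerance = 1e-3)
  expect_equal(u_end[2], 0)
  st0 <- final_state(tr); st0$u[] <- 0
  tr2 <- simulate(circ, drive = c(0, 0), t_end_ms = 10000, state0 = st0)
  expect_true(all(tr2$u == 0))
})
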