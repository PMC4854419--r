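test_that("the asymmetric-state condition reduces to beta f(S) > S > 0 without fatigue", {
  g <- gain_function("hard")
  # beta 2, S 1: 2 sqrt(1) = 2 > 1 > 0
  expect_true(asymmetric_condition(1, 0, 0, 1, 2, g))
  # boundary: S = 0 fails the strict S > a1 inequality
  expect_false(asymmetric_condition(0, 0, 0, 1, 2, g))
  # too-weak inhibition fails the suppression inequality
  expect_false(asymmetric_condition(4, 0, 0, 1, 0.5, g))
  expect_error(asymmetric_condition(1, 0, 0, 1, 0, g))
})

test_that("satisfaction at S_on implies satisfaction at any lower background", {
  # concavity argument, checked on a 6-decade log grid below S_on
  for (g in list(gain_function("hard"),
                 gain_function("smoothed", smoothing_scale = 1e-3))) {
    for (beta in c(1.5, 3)) {
      S_on <- 1
      stopifnot(asymmetric_condition(S_on, 0, 0, 1, beta, g))
      S_grid <- 10^seq(log10(S_on), log10(S_on) - 6, length.out = 200)
      expect_true(all(asymmetric_condition(S_grid, 0, 0, 1, beta, g)))
    }
  }
})

test_that("fixed points below threshold: unique stable rest state", {
  fp <- find_fixed_points(memory_profile$circuit, -0.5)
  expect_equal(nrow(fp), 1L)
  expect_equal(c(fp$u1, fp$u2), c(0, 0))
  expect_equal(fp$stability, "stable")
})

test_that("just above threshold: pitchfork structure with two stable asymmetric points", {
  fp <- find_fixed_points(memory_profile$circuit, 0.1)
  expect_equal(sum(fp$stability == "stable"), 2L)
  stable <- fp[fp$stability == "stable", ]
  expect_true(all(abs(stable$u1 - stable$u2) > 1e-3))
  sym <- fp[abs(fp$u1 - fp$u2) < 1e-9, ]
  expect_equal(sym$stability, "unstable")
  expect_true(all(fp$residual < 1e-10))
})

test_that("fixed-point sets are exchange symmetric", {
  for (S in c(0.12, 1, 5)) {
    fp <- find_fixed_points(memory_profile$circuit, S)
    swapped <- data.frame(u1 = fp$u2, u2 = fp$u1)
    for (i in seq_len(nrow(fp)))
      expect_true(any(abs(swapped$u1 - fp$u1) < 1e-8 &
                        abs(swapped$u2 - fp$u2) < 1e-8))
  }
})

test_that("the asymmetric branch exists at arbitrarily small positive drive", {
  # pitchfork at S = 0: asymmetric stable branch present for tiny S > 0,
  # absent at S <= 0 (hard gain, no fatigue)
  circ <- two_pool_circuit(inhibition = 2, ms_per_tau = 10)
  for (S in 10^c(-6, -4, -2)) {
    fp <- find_fixed_points(circ, S)
    expect_true(any(fp$stability == "stable" & abs(fp$u1 - fp$u2) > 0))
  }
  fp0 <- find_fixed_points(circ, 0)
  expect_false(any(fp0$stability == "stable" & abs(fp0$u1 - fp0$u2) > 1e-9))
})

test_that("stable fixed points agree with long simulations from random starts", {
  circ <- memory_profile$circuit
  S <- 0.12
  fp <- find_fixed_points(circ, S)
  stable <- fp[fp$stability == "stable", c("u1", "u2")]
  set.seed(3)
  ends <- t(replicate(12, {
    st <- circuit_state(runif(2), runif(2, 0, 0.3), matrix(1, 2, 2))
    final_state(simulate(circ, drive = c(S, S), t_end_ms = 2e5,
                         state0 = st))$u
  }))
  for (i in seq_len(nrow(ends))) {
    d <- apply(stable, 1, function(p) max(abs(ends[i, ] - p)))
    expect_lt(min(d), 1e-6)
  }
  # and every stable point is reached by at least one start
  for (j in seq_len(nrow(stable))) {
    d <- apply(ends, 1, function(e)
      max(abs(e - as.numeric(stable[j, ]))))
    expect_lt(min(d), 1e-6)
  }
})

test_that("regime scan orders symmetric, winner-take-all, rivalry with rising drive", {
  circ <- memory_profile$circuit
  circ$gain <- gain_function("smoothed", smoothing_scale = 1e-3)
  scan <- bifurcation_scan(circ, c(-0.2, 0.5, 3, 5, 6, 7),
                           cycle_window_tau_a = 25)
  reg <- scan$regimes$regime
  expect_equal(reg[1], "symmetric")
  expect_true(all(reg[2:3] == "winner-take-all"))
  expect_true("rivalry" %in% reg[5:6])
  # symmetric u1 - u2 = 0 branch exists at every S
  for (S in unique(scan$branches$S)) {
    b <- scan$branches[scan$branches$S == S, ]
    expect_true(any(abs(b$u1 - b$u2) < 1e-8))
  }
  expect_error(bifurcation_scan(circ, c(1, 0.5)), "increasing")
})

test_that("rivalry onset matches the asymmetric-condition boundary within grid resolution", {
  # independent computation: the largest S at which the memory condition
  # (with equilibrium local fatigue substituted) still holds
  circ <- memory_profile$circuit
  g <- circ$gain
  gam <- circ$local_fatigue
  beta <- abs(circ$weights[1, 2])
  holds <- function(S) {
    u1 <- stats::uniroot(function(u) u - gain_eval(g, S - gam * u),
                         c(0, 10))$root
    asymmetric_condition(S, gam * u1, 0, 1, beta, g)
  }
  S_grid <- seq(4, 7, by = 0.5)
  cond_boundary <- max(S_grid[vapply(S_grid, holds, logical(1))])
  scan <- bifurcation_scan(circ, S_grid, cycle_window_tau_a = 25)
  onset <- min(scan$regimes$S[scan$regimes$regime %in%
                                c("rivalry", "bistable")])
  expect_lte(abs(onset - cond_boundary), 2 * 0.5)
})

test_that("memory region: alternation at small intervals, none beyond the boundary", {
  pr <- memory_profile
  mr <- memory_region(pr$circuit, pr$S_on, c(200, 400, 700, 800),
                      pulse_width_ms = pr$pulse_width_ms, S_off = pr$S_off,
                      horizon_frames = 100)
  expect_true(mr$alternates[1])
  expect_false(mr$alternates[3])
  expect_false(mr$alternates[4])
  expect_equal(attr(mr, "boundary_ms"), 400)
  # zero background: alternation at every pulse for all frame intervals
  mr0 <- memory_region(pr$circuit, pr$S_on, c(200, 800),
                       pulse_width_ms = 20, S_off = 0, horizon_frames = 40)
  expect_true(all(mr0$alternates))
  expect_true(all(mr0$n_switches == 39))
})
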