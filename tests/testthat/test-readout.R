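mk_trace <- function(labels, pools = c("H", "V")) {
  structure(data.frame(time_ms = seq_along(labels) * 100, label = labels),
            class = c("percept_trace", "data.frame"), pool_labels = pools)
}

test_that("the most active pool gives the percept, with hysteresis on ties", {
  circ <- two_pool_circuit()
  traj <- list(circuit = circ,
               probes = list(times_ms = c(10, 20, 30, 40),
                             u = rbind(c(0.5, 0.1), c(0.3, 0.3),
                                       c(0.1, 0.6), c(0, 0)),
                             a = matrix(0, 4, 2), s = matrix(1, 4, 4)))
  class(traj) <- "rivalry_trajectory"
  tr <- dominant_labels(traj)
  expect_equal(tr$label, c("H", "H", "V", "none"))
  # initial tie goes to the lowest pool index
  traj$probes$u <- rbind(c(0.2, 0.2), c(0.2, 0.2))
  traj$probes$times_ms <- c(10, 20)
  traj$probes$a <- matrix(0, 2, 2); traj$probes$s <- matrix(1, 2, 4)
  expect_equal(dominant_labels(traj)$label, c("H", "H"))
})

test_that("dominance records run-length encode orientations with final censoring", {
  rec <- dominance_records(mk_trace(c("V", "V", "V", "H", "H")))
  expect_equal(rec$epoch, 1:2)
  expect_equal(rec$label, c("V", "H"))
  expect_equal(rec$T_D, c(3, 2))
  expect_equal(rec$censored, c(FALSE, TRUE))
  rec1 <- dominance_records(mk_trace("V"))
  expect_equal(rec1$T_D, 1)
  expect_true(rec1$censored)
  # alternation every transition: all durations one frame
  recA <- dominance_records(mk_trace(c("V", "H", "V", "H")))
  expect_equal(recA$T_D, rep(1, 4))
  expect_error(dominance_records(mk_trace(character(0))), "empty")
})

test_that("expanding dominance records reproduces the orientation sequence", {
  set.seed(42)
  for (i in 1:20) {
    labels <- sample(c("H", "V"), 30, replace = TRUE)
    rec <- dominance_records(mk_trace(labels))
    expect_equal(rep(rec$label, rec$T_D), rle(labels)$values[
      rep(seq_along(rle(labels)$lengths), rle(labels)$lengths)])
  }
})

test_that("quartet memory runs oscillate in direction while orientation persists", {
  pr <- rivalry_profile("quartet-memory")
  proto <- profile_protocol(pr, n_frames = 40)
  tr <- simulate(pr$circuit, protocol = proto,
                 state0 = kicked_state(pr$circuit))
  trace <- dominant_labels(tr)
  expect_true(rivalrymem:::quartet_trace_valid(trace))
  # first epoch: direction alternates every transition (V+, V-, V+, ...)
  first <- trace$label[1:6]
  expect_true(all(substr(first, 1, 1) == "V"))
  expect_true(all(substr(first[-1], 2, 2) != substr(first[-6], 2, 2)))
  rec <- dominance_records(trace)
  expect_gt(nrow(rec), 1) # orientation rivalry occurs
  expect_true(all(rec$label %in% c("H", "V", "rotation")))
  expect_true(all(rec$T_D[rec$label == "V"][1] > 1))
})

test_that("rotation stretches are detected and excluded from orientation epochs", {
  labels <- c("V+", "V-", "V+", "V-", # V oscillation
              "H+", "V+", "H+", "V+", "H+", # rotation (+ direction persists)
              "H-", "H+", "H-", # H oscillation
              "V+", "V-", "V+") # V again (censored)
  rec <- dominance_records(mk_trace(labels, pools = c("V+", "V-", "H+", "H-")))
  expect_equal(rec$label, c("V", "rotation", "H", "V"))
  expect_equal(rec$T_D, c(4, 5, 3, 3))
  hc <- habituation_curve(rec)
  # rotation epochs are excluded from the orientation duration summary
  expect_equal(hc$epoch, c(1, 3))
  expect_equal(hc$T_D, c(4, 3))
})

test_that("dynamic L4: dominance duration rises with frame interval, then no alternation", {
  pr <- memory_profile
  sw <- sweep_dynamic_L4(pr$circuit, c(pr$L4_grid_ms, pr$no_alt_T_frame_ms),
                         pulse_spec(pr$S_on, width_ms = pr$pulse_width_ms),
                         background_spec("fixed", S_off = pr$S_off),
                         horizon_frames = 100,
                         state0 = kicked_state(pr$circuit))
  alt <- !sw$no_alternation
  expect_false(is.unsorted(sw$mean_TD[alt]))
  expect_gt(max(diff(sw$mean_TD[alt])), 0) # strictly increases somewhere
  expect_true(sw$no_alternation[nrow(sw)])
  expect_error(sweep_dynamic_L4(pr$circuit, 300, pulse_spec(1, width_ms = 20),
                                background_spec("zero"),
                                horizon_frames = 0), "horizon")
})

test_that("zero background alternates on every pulse", {
  sw <- sweep_dynamic_L4(memory_profile$circuit, c(150, 300, 450),
                         pulse_spec(1, width_ms = 20),
                         background_spec("zero"), horizon_frames = 40,
                         state0 = kicked_state(memory_profile$circuit))
  expect_true(all(sw$mean_TD == 1))
  expect_true(all(sw$n_switches == 39))
})

test_that("habituation direction separates local from nonlocal fatigue", {
  e_local <- epoch_lengths(run_profile(memory_profile, n_frames = 120))
  expect_gt(e_local[1], e_local[2]) # strictly decreasing first step
  expect_true(all(diff(e_local) <= 0)) # non-increasing to steady state
  # deterministic steady state: late-epoch variance within one frame
  late <- e_local[max(1, length(e_local) - 5):length(e_local)]
  expect_lte(stats::var(late), 1)
  e_nonlocal <- epoch_lengths(run_profile(nonlocal_profile, n_frames = 120))
  expect_lt(e_nonlocal[1], e_nonlocal[2]) # first epoch shorter
})

test_that("habituation curve requires enough uncensored epochs", {
  rec <- dominance_records(mk_trace(c("V", "V")))
  expect_error(habituation_curve(rec), "uncensored")
})

test_that("switches classify as release under local and escape under nonlocal fatigue", {
  tr_l <- run_profile(memory_profile, n_frames = 60, record_every = 4)
  lab <- dominant_labels(tr_l)$label
  k <- which(lab[-1] != lab[-length(lab)])[1] + 1
  expect_equal(as.character(classify_switch(tr_l, k, memory_profile$S_on,
                                            memory_profile$S_off)),
               "release")
  tr_n <- run_profile(nonlocal_profile, n_frames = 60, record_every = 4)
  labn <- dominant_labels(tr_n)$label
  kn <- which(labn[-1] != labn[-length(labn)])[1] + 1
  expect_equal(as.character(classify_switch(tr_n, kn, nonlocal_profile$S_on,
                                            nonlocal_profile$S_off)),
               "escape")
  # calling at a non-switch transition (asymmetric state intact) errors
  expect_error(classify_switch(tr_l, k - 1, memory_profile$S_on,
                               memory_profile$S_off), "switch")
})
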