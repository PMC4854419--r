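#' Simulate a rivalry circuit
#'
#' Integrates the rate equations with a fixed-step fourth-order Runge-Kutta
#' scheme (compiled). The system is non-stiff at the model's time-scale
#' separation, and a fixed step keeps runs deterministic and reproducible;
#' the continuous (kinked) gain is integrated through without event
#' detection. The default step is one twentieth of the activity time
#' constant; steps above one tenth are refused.
#'
#' @param object a [rivalry_circuit()].
#' @param nsim unused (one trajectory per call); present for the generic.
#' @param seed optional integer seed, set before integration (gaussian
#'   background noise is drawn from R's RNG stream). If `NULL` and the
#'   protocol's background carries a seed, that seed is used.
#' @param protocol a [stimulus_protocol()] defining the pulsed drive, or
#'   `NULL` when `drive` is given.
#' @param drive alternative to `protocol`: a constant length-N drive vector
#'   (internal units), or a function `t_ms -> length-N vector` (integrated by
#'   an R-level RK4 of the same order; keep spans modest).
#' @param t_end_ms end of integration in ms (default: the protocol span).
#'   May exceed the span to observe off-state behaviour after the last pulse.
#' @param state0 initial [circuit_state()] (default: rested).
#' @param dt integration step in internal time units (tau_u = 1); must be
#'   <= 0.1.
#' @param record_every thin the stored trajectory to every k-th step
#'   (default: chosen so at most ~20000 points are kept; the final state is
#'   always stored exactly).
#' @param probe_times_ms times (ms) at which the exact (unthinned) state is
#'   additionally stored, e.g. percept decision times. When a protocol is
#'   given, its [decision_times()] are probed automatically.
#' @param ... unused.
#' @return An object of class `rivalry_trajectory`.
#' @export
simulate.rivalry_circuit <- function(object, nsim = 1, seed = NULL,
                                     protocol = NULL, drive = NULL,
                                     t_end_ms = NULL, state0 = NULL,
                                     dt = 0.05, record_every = NULL,
                                     probe_times_ms = NULL, ...) {
  circuit <- object
  if (dt <= 0 || dt > circuit$tau_u / 10)
    stop("dt must satisfy 0 < dt <= tau_u / 10 = ", circuit$tau_u / 10)
  if (is.null(protocol) == is.null(drive))
    stop("give exactly one of 'protocol' or 'drive'")
  if (is.null(state0)) state0 <- rested_state(circuit)
  stopifnot(inherits(state0, "circuit_state"))
  n <- circuit$n_pools
  if (length(state0$u) != n) stop("state0 dimension mismatch")
  mpt <- circuit$ms_per_tau

  if (!is.null(protocol)) {
    cp <- compile_protocol(protocol, circuit)
    if (is.null(t_end_ms)) t_end_ms <- protocol$span_ms
    if (is.null(probe_times_ms)) probe_times_ms <- decision_times(protocol)
    probe_times_ms <- probe_times_ms[probe_times_ms <= t_end_ms]
    if (is.null(seed) && !is.null(cp$seed)) seed <- cp$seed
  } else {
    if (is.null(t_end_ms)) stop("'t_end_ms' is required with a raw drive")
    if (is.numeric(drive)) {
      if (length(drive) != n) stop("constant drive must have one entry per pool")
      cp <- list(windows = matrix(0, 0, 2), amps = matrix(0, 0, n),
                 bg = as.numeric(drive), sigma = 0)
    } else {
      cp <- NULL # R-level path for functional drives
    }
  }

  n_steps <- ceiling((t_end_ms / mpt) / dt)
  if (n_steps < 1L) stop("t_end_ms too small: no integration steps")
  if (is.null(record_every))
    record_every <- max(1L, ceiling(n_steps / 20000))
  if (!is.null(seed)) set.seed(seed)

  if (!is.null(cp)) {
    probe_steps <- sort(unique(pmin(round((probe_times_ms / mpt) / dt),
                                    n_steps)))
    res <- .rate_sim_cpp(state0$u, state0$a, state0$s, circuit$weights,
                         circuit$local_fatigue, circuit$nonlocal_fatigue,
                         circuit$tau_a, circuit$tau_s,
                         match(circuit$gain$variant, c("hard", "smoothed")) - 1L,
                         circuit$gain$smoothing_scale, 0, dt,
                         as.integer(n_steps), cp$bg, cp$sigma,
                         cp$windows, cp$amps, as.integer(record_every),
                         as.numeric(probe_steps))
    probe_t <- probe_steps * dt * mpt
  } else {
    res <- rk4_r(circuit, state0, drive, dt, n_steps, record_every)
    probe_t <- numeric(0)
    probe_times_ms <- NULL
  }

  colnames(res$u) <- colnames(res$a) <- circuit$pool_labels
  structure(list(
    times_ms = res$times * mpt,
    u = res$u, a = res$a, s = res$s, drive = res$drive,
    probes = if (length(probe_t))
      list(times_ms = probe_t, requested_ms = probe_times_ms,
           u = res$probe_u, a = res$probe_a, s = res$probe_s)
    else NULL,
    circuit = circuit, protocol = protocol, dt = dt,
    record_every = record_every
  ), class = "rivalry_trajectory")
}

# R-level RK4 for arbitrary functional drives (same scheme as the compiled
# core; drive evaluated at each stage time)
rk4_r <- function(circuit, state0, drive_fn, dt, n_steps, record_every) {
  n <- circuit$n_pools
  mpt <- circuit$ms_per_tau
  g <- circuit$gain
  w <- circuit$weights
  gam <- circuit$local_fatigue; phi <- circuit$nonlocal_fatigue
  ta <- circuit$tau_a; ts <- circuit$tau_s
  f <- function(y, drv) {
    u <- y[1:n]; a <- y[(n + 1):(2 * n)]
    s <- matrix(y[-(1:(2 * n))], n, n)
    arg <- drv - gam * a + as.numeric((w * s) %*% u)
    c(-u + gain_eval(g, arg), (-a + u) / ta,
      (1 - s - phi * s * matrix(u, n, n, byrow = TRUE)) / ts)
  }
  y <- c(state0$u, state0$a, as.numeric(state0$s))
  keep <- unique(c(seq(0L, n_steps, by = record_every), n_steps))
  out_t <- numeric(length(keep))
  out <- matrix(NA_real_, length(keep), length(y))
  drv_log <- matrix(NA_real_, length(keep), n)
  rec <- 1L
  for (step in 0:n_steps) {
    t <- step * dt
    if (step %in% keep) {
      out_t[rec] <- t; out[rec, ] <- y
      drv_log[rec, ] <- drive_fn(t * mpt)
      rec <- rec + 1L
    }
    if (step == n_steps) break
    d1 <- drive_fn(t * mpt)
    d2 <- drive_fn((t + dt / 2) * mpt)
    d3 <- drive_fn((t + dt) * mpt)
    k1 <- f(y, d1)
    k2 <- f(y + dt / 2 * k1, d2)
    k3 <- f(y + dt / 2 * k2, d2)
    k4 <- f(y + dt * k3, d3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[1:(2 * n)][y[1:(2 * n)] < 0 & y[1:(2 * n)] > -1e-12] <- 0
    if (any(!is.finite(y)))
      stop("integration diverged: non-finite state at t = ", t * mpt, " ms")
  }
  list(times = out_t, u = out[, 1:n, drop = FALSE],
       a = out[, (n + 1):(2 * n), drop = FALSE],
       s = out[, -(1:(2 * n)), drop = FALSE], drive = drv_log)
}

#' Final state of a trajectory
#'
#' The exact state at the last integration step, usable as `state0` for a
#' continuation run (e.g. resuming stimulation after a long off-gap).
#'
#' @param traj a `rivalry_trajectory`.
#' @return A [circuit_state()].
#' @export
final_state <- function(traj) {
  n <- traj$circuit$n_pools
  k <- nrow(traj$u)
  u <- pmax(traj$u[k, ], 0)
  a <- pmax(traj$a[k, ], 0)
  s <- matrix(pmin(pmax(traj$s[k, ], .Machine$double.eps), 1), n, n)
  circuit_state(u, a, s)
}

#' Interpolated state at arbitrary times
#'
#' Linear interpolation of the recorded trajectory. Decision-time readout
#' should prefer the exact probes stored by [simulate.rivalry_circuit()].
#'
#' @param traj a `rivalry_trajectory`.
#' @param t_ms times in ms within the trajectory span.
#' @return List with matrices `u`, `a` (rows = times) and `s`.
#' @export
state_at <- function(traj, t_ms) {
  if (any(t_ms < traj$times_ms[1] | t_ms > max(traj$times_ms)))
    stop("time outside trajectory span")
  ip <- function(m) apply(m, 2, function(col)
    stats::approx(traj$times_ms, col, xout = t_ms)$y)
  u <- ip(traj$u); a <- ip(traj$a); s <- ip(traj$s)
  if (length(t_ms) == 1L) {
    u <- matrix(u, 1); a <- matrix(a, 1); s <- matrix(s, 1)
  }
  list(u = u, a = a, s = s)
}

#' @export
print.rivalry_trajectory <- function(x, ...) {
  cat(sprintf(
    "rivalry trajectory: %d pools, %g ms (%d stored points, dt = %g tau_u)\n",
    x$circuit$n_pools, max(x$times_ms), length(x$times_ms), x$dt))
  k <- nrow(x$u)
  cat("  final u:", paste(sprintf("%s = %.4f", x$circuit$pool_labels,
                                  x$u[k, ]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rivalry_trajectory <- function(x, ...) {
  n <- x$circuit$n_pools
  data.frame(
    time_ms = rep(x$times_ms, n),
    pool = rep(x$circuit$pool_labels, each = length(x$times_ms)),
    u = as.numeric(x$u), a = as.numeric(x$a),
    drive = as.numeric(x$drive))
}

#' @export
plot.rivalry_trajectory <- function(x, ...) {
  graphics::matplot(x$times_ms, x$u, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "pool activity u", ...)
  graphics::legend("topright", legend = x$circuit$pool_labels,
                   col = seq_len(x$circuit$n_pools), lty = 1, bty = "n")
  invisible(x)
}
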