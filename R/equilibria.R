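#' Existence condition for the asymmetric (memory) state
#'
#' The asymmetric fixed point of the two-pool circuit (pool 1 active at
#' `u1 = f(S - a1) > 0`, pool 2 silent) exists iff
#' `s1 * beta * f(S - a1) + a2 > S > a1`, with `beta` the inhibition
#' *magnitude*: the first inequality keeps the suppressed pool below
#' threshold, the second keeps the dominant pool active. With no fatigue
#' (`s1 = 1`, `a1 = a2 = 0`) the condition reduces to `beta * f(S) > S > 0`;
#' for a concave gain with `f(0) = 0`, satisfaction at `S_on` implies
#' satisfaction at every `0 < S_off <= S_on` — the basis of
#' mutual-inhibition rivalry memory at arbitrarily low background input.
#' Fatigue terms should be passed pre-scaled by the local fatigue strength.
#'
#' @param S input level.
#' @param a1,a2 (scaled) local fatigue of the dominant / suppressed pool.
#' @param s1 nonlocal fatigue (synaptic scaling) of the dominant pool's
#'   outgoing inhibition, in (0, 1].
#' @param beta_mag inhibition magnitude (> 0).
#' @param gain a [gain_function()].
#' @return `TRUE` iff both strict inequalities hold.
#' @export
asymmetric_condition <- function(S, a1, a2, s1, beta_mag, gain) {
  stopifnot(beta_mag > 0)
  (s1 * beta_mag * gain_eval(gain, S - a1) + a2 > S) & (S > a1)
}

# equilibrium fatigue closure: a_i = u_i, s_ij = 1/(1 + phi * u_j)
fatigue_closure <- function(circuit, u) {
  n <- circuit$n_pools
  list(a = u,
       s = matrix(1 / (1 + circuit$nonlocal_fatigue * rep(u, each = n)),
                  n, n))
}

# gain argument per pool at equilibrium-closed state
fp_args <- function(circuit, u, S) {
  cl <- fatigue_closure(circuit, u)
  S - circuit$local_fatigue * u +
    as.numeric((circuit$weights * cl$s) %*% u)
}

fp_residual <- function(circuit, u, S) {
  u - gain_eval(circuit$gain, fp_args(circuit, u, S))
}

# all roots of a scalar function on (lo, hi] via grid sign scan + uniroot
scalar_roots <- function(fn, lo, hi, n_grid = 400, tol = 1e-12) {
  xs <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(xs, fn, numeric(1))
  roots <- xs[ys == 0]
  idx <- which(ys[-1] * ys[-n_grid] < 0)
  for (i in idx)
    roots <- c(roots, stats::uniroot(fn, c(xs[i], xs[i + 1]),
                                     tol = tol)$root)
  roots
}

# full-system Jacobian (u, a, s) at an equilibrium, by central differences
# of the model right-hand side; NULL if the state sits on a gain kink
fp_jacobian <- function(circuit, u, S) {
  n <- circuit$n_pools
  if (any(abs(fp_args(circuit, u, S)) < 1e-8)) return(NULL)
  cl <- fatigue_closure(circuit, u)
  y0 <- c(u, cl$a, as.numeric(cl$s))
  dim_y <- length(y0)
  rhs <- function(y) {
    st <- list(u = pmax(y[1:n], 0), a = y[(n + 1):(2 * n)],
               s = matrix(y[-(1:(2 * n))], n, n))
    d <- circuit_derivatives(structure(st, class = "circuit_state"),
                             rep(S, n), circuit)
    c(d$du, d$da, as.numeric(d$ds))
  }
  J <- matrix(0, dim_y, dim_y)
  for (k in seq_len(dim_y)) {
    h <- 1e-7 * max(1, abs(y0[k]))
    yp <- y0; yp[k] <- yp[k] + h
    ym <- y0; ym[k] <- ym[k] - h
    J[, k] <- (rhs(yp) - rhs(ym)) / (2 * h)
  }
  J
}

#' Fixed points of the two-pool circuit at static drive
#'
#' Enumerates the possible active sets (neither, either, both pools active)
#' with the slow fatigue variables at their drive-consistent equilibria
#' (`a_i = u_i`, `s_ij = 1 / (1 + phi u_j)`), solves each support by
#' one-dimensional root bracketing (plus a damped Newton pass from a lattice
#' of starts for both-active asymmetric states), verifies consistency
#' (inactive pools must have gain argument <= 0), and classifies stability
#' by the eigenvalues of the full (u, a, s) Jacobian. Points lying exactly
#' on the gain threshold kink are reported `"marginal"`.
#'
#' @param circuit a 2-pool `rivalry_circuit`.
#' @param S static symmetric drive (internal units).
#' @param tol residual tolerance for accepting a fixed point.
#' @return Data frame of class `fixed_points`: `u1`, `u2`, `a1`, `a2`,
#'   `s21`, `s12`, `active_set`, `stability`, `leading_ev`, `residual`.
#' @export
find_fixed_points <- function(circuit, S, tol = 1e-10) {
  if (circuit$n_pools != 2L)
    stop("fixed-point enumeration is implemented for two-pool circuits")
  g <- circuit$gain
  pos_sum <- max(0, sum(pmax(circuit$weights, 0)))
  umax <- 1.5 * (pos_sum + sqrt(pos_sum^2 + 4 * max(S, 0) +
                                  4 * g$smoothing_scale)) / 2 + 1
  cand <- list()
  add <- function(u) cand[[length(cand) + 1L]] <<- u

  # empty support
  if (gain_eval(g, S) <= 0) add(c(0, 0))
  # single-pool supports
  for (active in 1:2) {
    fn <- function(x) {
      u <- c(0, 0); u[active] <- x
      fp_residual(circuit, u, S)[active]
    }
    for (r in scalar_roots(fn, 1e-9, umax)) {
      u <- c(0, 0); u[active] <- r
      if (fp_args(circuit, u, S)[3 - active] <= 1e-9) add(u)
    }
  }
  # both active, symmetric diagonal
  fn_sym <- function(x) fp_residual(circuit, c(x, x), S)[1]
  for (r in scalar_roots(fn_sym, 1e-9, umax))
    if (all(fp_args(circuit, c(r, r), S) > 0)) add(c(r, r))
  # both active, asymmetric: damped Newton from a lattice of starts
  starts <- as.matrix(expand.grid(seq(0.05, umax, length.out = 8),
                                  seq(0.05, umax, length.out = 8)))
  for (i in seq_len(nrow(starts))) {
    u <- starts[i, ]
    ok <- FALSE
    for (it in 1:60) {
      r <- fp_residual(circuit, u, S)
      if (any(!is.finite(r))) break
      if (max(abs(r)) < tol) { ok <- TRUE; break }
      h <- 1e-7
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        up <- u; up[k] <- up[k] + h
        um <- u; um[k] <- um[k] - h
        J[, k] <- (fp_residual(circuit, up, S) -
                     fp_residual(circuit, um, S)) / (2 * h)
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(pmax(step, -0.5), 0.5)
      u <- pmin(pmax(u - step, 1e-9), umax)
    }
    if (ok && all(u > 1e-7) && all(fp_args(circuit, u, S) > 0)) add(u)
  }

  if (!length(cand)) return(empty_fixed_points())
  U <- do.call(rbind, cand)
  # dedupe without perturbing the roots (the gain slope can be steep)
  keep <- rep(TRUE, nrow(U))
  for (i in seq_len(nrow(U))[-1])
    if (any(vapply(seq_len(i - 1L)[keep[seq_len(i - 1L)]], function(j)
      max(abs(U[i, ] - U[j, ])) < 1e-7, logical(1)))) keep[i] <- FALSE
  U <- U[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(U)), function(i) {
    u <- pmax(U[i, ], 0)
    res <- max(abs(fp_residual(circuit, u, S)))
    if (res > 1e3 * tol) return(NULL)
    cl <- fatigue_closure(circuit, u)
    J <- fp_jacobian(circuit, u, S)
    if (is.null(J)) {
      stab <- "marginal"; lev <- NA_real_
    } else {
      ev <- eigen(J, only.values = TRUE)$values
      lev <- max(Re(ev))
      stab <- if (lev < -1e-8) "stable" else if (lev > 1e-8) "unstable"
      else "marginal"
    }
    data.frame(u1 = u[1], u2 = u[2], a1 = cl$a[1], a2 = cl$a[2],
               s21 = cl$s[2, 1], s12 = cl$s[1, 2],
               active_set = paste(which(u > 1e-9), collapse = ","),
               stability = stab, leading_ev = lev, residual = res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_fixed_points())
  out <- out[order(out$u1 - out$u2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("fixed_points", "data.frame"))
}

empty_fixed_points <- function() {
  structure(data.frame(u1 = numeric(0), u2 = numeric(0), a1 = numeric(0),
                       a2 = numeric(0), s21 = numeric(0), s12 = numeric(0),
                       active_set = character(0), stability = character(0),
                       leading_ev = numeric(0), residual = numeric(0)),
            class = c("fixed_points", "data.frame"))
}

# limit-cycle detection by simulation: switch counting on u1 - u2 with an
# amplitude guard; present iff >= 4 switches with period CV < 10%
detect_limit_cycle <- function(circuit, S, transient_tau_a = 10,
                               window_tau_a = 50, dt = 0.05) {
  u0 <- max(gain_eval(circuit$gain, S), 0.2)
  st <- circuit_state(c(u0, 0.3 * u0), c(0.5 * u0, 0.2 * u0),
                      matrix(1, 2, 2))
  mpt <- circuit$ms_per_tau
  t_tr <- transient_tau_a * circuit$tau_a * mpt
  tr <- simulate(circuit, drive = rep(S, 2), t_end_ms = t_tr, state0 = st,
                 dt = dt)
  tr2 <- simulate(circuit, drive = rep(S, 2),
                  t_end_ms = window_tau_a * circuit$tau_a * mpt,
                  state0 = final_state(tr), dt = dt)
  d <- tr2$u[, 1] - tr2$u[, 2]
  amp <- max(abs(d))
  if (amp < 1e-4)
    return(list(present = FALSE, period_ms = NA_real_, amplitude = amp))
  thr <- 0.05 * amp
  sgn <- sign(d) * (abs(d) > thr)
  sgn <- sgn[sgn != 0]
  times <- tr2$times_ms[abs(d) > thr]
  flips <- which(diff(sgn) != 0)
  if (length(flips) < 4)
    return(list(present = FALSE, period_ms = NA_real_, amplitude = amp))
  ft <- times[flips + 1]
  half <- diff(ft)
  cv <- stats::sd(half) / mean(half)
  list(present = is.finite(cv) && cv < 0.1,
       period_ms = 2 * mean(half), amplitude = amp)
}

#' Bifurcation scan of the two-pool circuit over static drive
#'
#' For each drive level `S` on an increasing grid, enumerates fixed points
#' ([find_fixed_points()]), detects rivalry limit cycles by simulation
#' (switch counting with a period-regularity requirement), and labels the
#' regime: `"symmetric"` (only the symmetric state is stable),
#' `"winner-take-all"` (a stable asymmetric state exists), `"rivalry"` (a
#' limit cycle, no stable symmetric state) or `"bistable"` (limit cycle
#' coexisting with a stable symmetric state). The canonical ordering with
#' increasing `S` is symmetric, winner-take-all (pitchfork at `S = 0`),
#' then rivalry (saddle-node on the limit cycle).
#'
#' @param circuit a 2-pool `rivalry_circuit`.
#' @param S_grid increasing drive levels.
#' @param detect_cycles simulate for limit cycles (slower); if `FALSE`,
#'   regimes are labelled from fixed points alone.
#' @param cycle_window_tau_a simulation window for cycle detection, in
#'   units of `tau_a`.
#' @return A list of class `regime_scan`: `branches` (per-S fixed points),
#'   `regimes` (per-S summary with cycle period/amplitude and label).
#' @export
bifurcation_scan <- function(circuit, S_grid, detect_cycles = TRUE,
                             cycle_window_tau_a = 50) {
  if (is.unsorted(S_grid, strictly = TRUE)) stop("S_grid must be increasing")
  branches <- list()
  regimes <- list()
  for (S in S_grid) {
    fp <- find_fixed_points(circuit, S)
    if (nrow(fp)) fp <- cbind(S = S, fp, branch = seq_len(nrow(fp)))
    asym_stable <- nrow(fp) > 0 &&
      any(fp$stability == "stable" & abs(fp$u1 - fp$u2) > 1e-6)
    sym_stable <- nrow(fp) > 0 &&
      any(fp$stability == "stable" & abs(fp$u1 - fp$u2) <= 1e-6)
    cyc <- if (detect_cycles && S > 0)
      detect_limit_cycle(circuit, S, window_tau_a = cycle_window_tau_a)
    else list(present = FALSE, period_ms = NA_real_, amplitude = NA_real_)
    regime <- if (cyc$present && sym_stable) "bistable"
      else if (cyc$present && !asym_stable) "rivalry"
      else if (asym_stable) "winner-take-all"
      else "symmetric"
    branches[[length(branches) + 1L]] <- fp
    regimes[[length(regimes) + 1L]] <- data.frame(
      S = S, cycle = cyc$present, period_ms = cyc$period_ms,
      amplitude = cyc$amplitude, n_fixed_points = nrow(fp),
      regime = regime)
  }
  structure(list(branches = do.call(rbind, branches[lengths(branches) > 0]),
                 regimes = do.call(rbind, regimes)),
            class = "regime_scan")
}

#' @export
print.regime_scan <- function(x, ...) {
  cat("bifurcation scan over", nrow(x$regimes), "drive levels\n")
  r <- rle(x$regimes$regime)
  lo <- cumsum(r$lengths) - r$lengths + 1L
  hi <- cumsum(r$lengths)
  for (i in seq_along(r$values))
    cat(sprintf("  S in [%g, %g]: %s\n", x$regimes$S[lo[i]],
                x$regimes$S[hi[i]], r$values[i]))
  invisible(x)
}

#' @export
as.data.frame.regime_scan <- function(x, ...) {
  b <- x$branches
  data.frame(S = b$S, branch = b$branch, u1 = b$u1, u2 = b$u2,
             du = b$u1 - b$u2, stability = b$stability,
             regime = x$regimes$regime[match(b$S, x$regimes$S)])
}

#' Alternation map over frame intervals (memory region)
#'
#' Runs the intermittent protocol at each frame interval and reports
#' whether any dominance alternation occurred within the horizon. The
#' memory-region boundary is the largest alternating `T_frame`: beyond it,
#' fatigue decays faster between pulses than it accumulates, and the last
#' dominant percept holds for the whole run.
#'
#' @param circuit a `rivalry_circuit`.
#' @param S_on pulse amplitude.
#' @param T_frame_grid_ms frame intervals to test.
#' @param pulse_width_ms pulse width (fixed across the grid).
#' @param S_off fixed background level.
#' @param horizon_frames frames per run.
#' @return Data frame `T_frame_ms`, `alternates`, `n_switches`, with
#'   attribute `boundary_ms` (largest alternating interval, or `NA`).
#' @export
memory_region <- function(circuit, S_on, T_frame_grid_ms,
                          pulse_width_ms = 20, S_off = 0.12,
                          horizon_frames = 150) {
  sw <- sweep_dynamic_L4(circuit, T_frame_grid_ms,
                         pulse_spec(S_on, width_ms = pulse_width_ms),
                         background_spec("fixed", S_off = S_off),
                         horizon_frames = horizon_frames)
  out <- data.frame(T_frame_ms = sw$T_frame_ms,
                    alternates = !sw$no_alternation,
                    n_switches = sw$n_switches)
  attr(out, "boundary_ms") <- if (any(out$alternates))
    max(out$T_frame_ms[out$alternates]) else NA_real_
  out
}
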