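#' Percept labels at frame transitions
#'
#' The most active pool at each decision time gives the percept. Decision
#' times default to the end of each pulse window (largest, near-stationary
#' activity imbalance), taken from the exact-state probes stored by
#' [simulate.rivalry_circuit()]. Ties (activity difference below `tol`)
#' retain the previous label, mirroring perceptual hysteresis; an initial
#' tie goes to the lowest pool index. If all activities are numerically zero
#' the transition is labelled `"none"` and later excluded from dominance
#' durations.
#'
#' @param traj a `rivalry_trajectory` (simulated from a protocol).
#' @param decision_times_ms decision times in ms; default: the trajectory's
#'   stored probe times.
#' @param tol tie tolerance on the activity difference.
#' @return A data frame of class `percept_trace` with columns `time_ms` and
#'   `label`.
#' @export
dominant_labels <- function(traj, decision_times_ms = NULL, tol = 1e-9) {
  labs <- traj$circuit$pool_labels
  if (is.null(decision_times_ms)) {
    if (is.null(traj$probes))
      stop("trajectory has no stored decision probes; pass decision_times_ms")
    u <- traj$probes$u
    times <- traj$probes$times_ms
  } else {
    if (any(decision_times_ms < traj$times_ms[1] |
            decision_times_ms > max(traj$times_ms)))
      stop("decision times outside the trajectory span")
    u <- state_at(traj, decision_times_ms)$u
    times <- decision_times_ms
  }
  n <- nrow(u)
  lab <- character(n)
  prev <- NA_character_
  for (k in seq_len(n)) {
    if (max(u[k, ]) < 1e-8) { lab[k] <- "none"; next }
    ord <- order(u[k, ], decreasing = TRUE)
    if (length(labs) > 1 && u[k, ord[1]] - u[k, ord[2]] < tol) {
      lab[k] <- if (is.na(prev)) labs[min(ord[1:2])] else prev
    } else {
      lab[k] <- labs[ord[1]]
    }
    prev <- lab[k]
  }
  structure(data.frame(time_ms = times, label = lab),
            class = c("percept_trace", "data.frame"),
            pool_labels = labs)
}

#' Allowed quartet percept transitions
#'
#' The symmetries of the quartet illusion restrict which percept can follow
#' which: each frame transition alternates the stimulated parity, so a
#' percept of one direction/orientation combination can only be followed by
#' the same orientation with flipped direction (continuing oscillation) or
#' the flipped orientation with the same direction (rotation continues).
#'
#' @return A 4 x 4 0/1 matrix; rows = current percept, columns = allowed
#'   next percept.
#' @export
quartet_transition_table <- function() {
  lab <- c("V+", "V-", "H+", "H-")
  m <- matrix(0L, 4, 4, dimnames = list(lab, lab))
  m["V+", c("V-", "H+")] <- 1L
  m["V-", c("V+", "H-")] <- 1L
  m["H+", c("H-", "V+")] <- 1L
  m["H-", c("H+", "V-")] <- 1L
  m
}

# does a quartet trace respect the allowed-transition table?
quartet_trace_valid <- function(trace) {
  lab <- trace$label[trace$label != "none"]
  if (length(lab) < 2) return(TRUE)
  tab <- quartet_transition_table()
  all(tab[cbind(lab[-length(lab)], lab[-1])] == 1L)
}

# orientation (H/V) per quartet label, with rotation segments detected:
# a stretch of >= min_run transitions with constant direction and strictly
# alternating orientation is a rotation percept
orientation_sequence <- function(labels, min_run = 4L) {
  if (!any(grepl("[+-]$", labels))) return(labels) # two-pool trace
  ori <- substr(labels, 1, 1)
  dir <- substr(labels, 2, 2)
  out <- ori
  r <- rle(dir)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in seq_along(r$lengths)) {
    if (r$lengths[seg] < min_run) next
    idx <- starts[seg]:ends[seg]
    if (all(ori[idx][-1] != ori[idx][-length(idx)]))
      out[idx] <- "rotation"
  }
  out
}

#' Dominance records from a percept trace
#'
#' Run-length encodes the orientation percept sequence into dominance
#' records: epoch (1-based order), label, duration `T_D` in movie frames
#' (consecutive transitions with the same orientation), and a censoring
#' flag. Quartet direction labels are grouped to their orientation (`V+`,
#' `V-` -> `V`); direction-persistent stretches are detected and labelled
#' `"rotation"` (excluded from orientation duration summaries downstream).
#' The final record of every run is censored: the percept was still dominant
#' when the run ended, so its duration is only a lower bound — matching the
#' treatment of block ends in the survival analysis.
#'
#' @param trace a [dominant_labels()] trace.
#' @return Data frame with columns `epoch`, `label`, `T_D`, `censored`.
#' @export
dominance_records <- function(trace) {
  lab <- trace$label[trace$label != "none"]
  if (length(lab) == 0) stop("empty percept trace")
  ori <- orientation_sequence(lab)
  r <- rle(ori)
  n <- length(r$lengths)
  data.frame(epoch = seq_len(n), label = r$values, T_D = r$lengths,
             censored = c(rep(FALSE, n - 1L), TRUE))
}

#' Dynamic-L4 sweep over frame intervals
#'
#' Runs the intermittent protocol at each `T_frame`, scores dominance
#' durations, and summarises the mean uncensored orientation `T_D` (in
#' frames) per `T_frame`. A `no_alternation` flag marks frame intervals at
#' which no percept switch occurred within the horizon. Dynamic L4 is the
#' non-decreasing dependence of `T_D` on `T_frame`, with a no-alternation
#' region at large intervals.
#'
#' @param circuit a `rivalry_circuit`.
#' @param T_frame_grid_ms increasing frame intervals to test (ms).
#' @param pulse a [pulse_spec()].
#' @param background a [background_spec()].
#' @param horizon_frames number of frame transitions per run (>= 1).
#' @param state0 initial state (default: [kicked_state()]).
#' @param seed optional seed (gaussian background).
#' @return Data frame with columns `T_frame_ms`, `mean_TD`, `n_switches`,
#'   `no_alternation`.
#' @export
sweep_dynamic_L4 <- function(circuit, T_frame_grid_ms, pulse, background,
                             horizon_frames = 150, state0 = NULL,
                             seed = NULL) {
  if (horizon_frames < 1) stop("horizon shorter than one frame")
  if (is.null(state0)) state0 <- kicked_state(circuit)
  out <- lapply(T_frame_grid_ms, function(Tf) {
    proto <- stimulus_protocol(frame_sequence(Tf, horizon_frames), pulse,
                               background)
    tr <- simulate(circuit, protocol = proto, state0 = state0, seed = seed)
    rec <- dominance_records(dominant_labels(tr))
    unc <- rec[!rec$censored & rec$label != "rotation", ]
    data.frame(T_frame_ms = Tf,
               mean_TD = if (nrow(unc)) mean(unc$T_D) else NA_real_,
               n_switches = nrow(rec) - 1L,
               no_alternation = nrow(rec) == 1L)
  })
  do.call(rbind, out)
}

#' Habituation curve: dominance duration by percept epoch
#'
#' @param records a [dominance_records()] data frame.
#' @return Data frame `epoch`, `T_D` for the uncensored orientation epochs.
#' @export
habituation_curve <- function(records) {
  unc <- records[!records$censored & records$label != "rotation", ]
  if (nrow(unc) < 2)
    stop("need at least 2 uncensored dominance records for a habituation curve")
  data.frame(epoch = unc$epoch, T_D = unc$T_D)
}

#' Classify a dominance switch as escape or release
#'
#' The asymmetric (one pool dominant) state of the two-pool circuit requires
#' both `s1 * beta * f(S - a1) + a2 > S` evaluated at the on-state input
#' (enough inhibition to suppress the inactive pool) and `S_off > a1`
#' (little enough fatigue for the dominant pool to stay active on background
#' input), with fatigue terms scaled by the local fatigue strength. A switch
#' through failure of the first clause is an *escape* (inhibition too weak
#' to hold the suppressed pool down); failure of the second is a *release*
#' (the dominant pool can no longer remain active). Clauses are evaluated
#' just before the pulse at which the label changes.
#'
#' @param traj a two-pool `rivalry_trajectory` simulated from a protocol.
#' @param switch_index index `k` into the percept trace such that the label
#'   at transition `k` differs from that at `k - 1`.
#' @param S_on,S_off on-state and background input levels used in the run.
#' @return `"escape"` or `"release"`, with attributes `escape_margin` and
#'   `release_margin` (negative = clause failed). If both clauses fail, the
#'   more strongly violated one is returned.
#' @export
classify_switch <- function(traj, switch_index, S_on, S_off) {
  circuit <- traj$circuit
  if (circuit$n_pools != 2L)
    stop("switch classification is defined for the reduced two-pool circuit")
  trace <- dominant_labels(traj)
  k <- as.integer(switch_index)
  if (k < 2L || k > nrow(trace)) stop("switch_index out of range")
  if (trace$label[k] == trace$label[k - 1L])
    stop("no labelled switch at transition ", k)
  dom <- match(trace$label[k - 1L], circuit$pool_labels)
  sup <- 3L - dom
  # evaluate both clauses over the window between the last pre-switch
  # decision and the switching decision: the actual flip (dominant pool
  # dying, or suppressed pool breaking through) happens inside it
  t0 <- trace$time_ms[k - 1L]
  t1 <- trace$time_ms[k]
  idx <- traj$times_ms >= t0 & traj$times_ms <= t1
  if (sum(idx) < 3) stop("trajectory stored too coarsely around the switch")
  gam <- circuit$local_fatigue
  b <- abs(circuit$weights[sup, dom])
  n <- circuit$n_pools
  s_col <- (dom - 1L) * n + sup # column-major s[sup, dom]
  a1v <- gam * traj$a[idx, dom]
  a2v <- gam * traj$a[idx, sup]
  s1v <- traj$s[idx, s_col]
  esc <- min(s1v * b * gain_eval(circuit$gain, S_on - a1v) + a2v - S_on)
  rel <- min(S_off - a1v)
  if (rel <= 0 && (esc > 0 || rel < esc)) {
    cls <- "release"
  } else if (esc <= 0) {
    cls <- "escape"
  } else {
    # neither quasi-static clause strictly failed: under pulsed input the
    # suppressed pool can win the on-state race slightly before the
    # equilibrium inhibition condition fails. If the dominant pool's
    # off-state activity persisted through the window (its memory state was
    # intact), the transfer is the realized form of inhibition failure.
    u_dom_off <- traj$u[idx, dom][a1v < S_off]
    if (length(u_dom_off) && min(u_dom_off) > 1e-6) {
      cls <- "escape"
    } else {
      stop("neither switch clause failed just before transition ", k,
           ": not a true asymmetric-state switch")
    }
  }
  structure(cls, escape_margin = esc, release_margin = rel)
}
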