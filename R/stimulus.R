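#' Frame sequence of the intermittent stimulus
#'
#' The quartet animation alternates between two dot parities: `UR-LL`
#' (upper-right / lower-left) and `LR-UL` (lower-right / upper-left). Each
#' frame transition is a percept-inducing event; a change-detecting network
#' converts it into a brief input pulse to the model. `n_frames` counts frame
#' transitions (= input pulses), which occur at times `0, T_frame,
#' 2 T_frame, ...`.
#'
#' @param T_frame_ms frame interval in ms (> 0).
#' @param n_frames number of frame transitions (>= 1).
#' @param start_parity parity shown before the first transition, `"UR-LL"`
#'   (default) or `"LR-UL"`; parities strictly alternate thereafter.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(T_frame_ms, n_frames,
                           start_parity = c("UR-LL", "LR-UL")) {
  start_parity <- match.arg(start_parity)
  if (!is.numeric(T_frame_ms) || T_frame_ms <= 0) stop("T_frame_ms must be > 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(T_frame_ms = T_frame_ms, n_frames = n_frames,
                 start_parity = start_parity), class = "frame_sequence")
}

#' Input pulse during a frame transition
#'
#' @param S_on on-state input amplitude (> 0, internal drive units).
#' @param width_ms pulse duration in ms, or `NULL` to default to
#'   `0.25 * T_frame` when the protocol is assembled. The calibrated
#'   "paper-like" profiles use a fixed width independent of `T_frame`,
#'   modelling the change-detector transient as a physiological constant.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(S_on, width_ms = NULL) {
  if (!is.numeric(S_on) || S_on <= 0) stop("S_on must be > 0")
  if (!is.null(width_ms) && (!is.numeric(width_ms) || width_ms <= 0))
    stop("width_ms must be > 0 (or NULL for the 0.25 * T_frame default)")
  structure(list(S_on = S_on, width_ms = width_ms), class = "pulse_spec")
}

#' Nonspecific background input in the off-state
#'
#' Background drive `S_off` received by every pool between (and, additively,
#' during) pulses: `"zero"` (no background), `"fixed"` (constant `S_off >=
#' 0`), or `"gaussian"` (zero-mean noise `N(0, sigma^2)`, redrawn
#' independently per pool at every integrator step and held constant within
#' the step; the threshold gain rectifies it into an effective positive
#' background).
#'
#' @param mode `"zero"`, `"fixed"` or `"gaussian"`.
#' @param S_off fixed background level (>= 0; `"fixed"` mode).
#' @param sigma noise standard deviation (> 0; `"gaussian"` mode).
#' @param seed optional integer seed for the gaussian stream; identical seeds
#'   reproduce identical streams bit-for-bit.
#' @return An object of class `background_spec`.
#' @export
background_spec <- function(mode = c("zero", "fixed", "gaussian"),
                            S_off = 0, sigma = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.numeric(S_off) || S_off < 0))
    stop("fixed background requires S_off >= 0")
  if (mode == "gaussian" &&
      (is.null(sigma) || !is.numeric(sigma) || sigma <= 0))
    stop("gaussian background requires sigma > 0")
  structure(list(mode = mode,
                 S_off = if (mode == "fixed") as.numeric(S_off) else 0,
                 sigma = if (mode == "gaussian") as.numeric(sigma) else 0,
                 seed = seed), class = "background_spec")
}

#' Pools driven by a quartet frame transition
#'
#' A transition from `UR-LL` to `LR-UL` stimulates the pools consistent with
#' that motion, `V+` and `H-`; the reverse transition stimulates `V-` and
#' `H+`.
#'
#' @param parity_from,parity_to the two frame parities (must differ).
#' @return Character vector of driven pool labels.
#' @export
transition_drive <- function(parity_from, parity_to) {
  ok <- c("UR-LL", "LR-UL")
  if (!parity_from %in% ok || !parity_to %in% ok) stop("unknown parity")
  if (parity_from == parity_to)
    stop("identical parities: no frame transition, no drive")
  if (parity_from == "UR-LL") c("V+", "H-") else c("V-", "H+")
}

#' Intermittent stimulation protocol
#'
#' Combines a frame sequence, a pulse spec and a background spec into the
#' time-dependent drive `S_i(t)`. For a two-pool circuit both pools are
#' pulsed simultaneously at each frame transition (the direction oscillation
#' is averaged out); for a quartet circuit each transition pulses the two
#' transition-consistent pools (see [transition_drive()]), the other two
#' receive background only. Background is present at all times, additively
#' during pulses.
#'
#' @param frames a [frame_sequence()].
#' @param pulse a [pulse_spec()].
#' @param background a [background_spec()] (default: zero).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(frames, pulse, background = background_spec()) {
  stopifnot(inherits(frames, "frame_sequence"), inherits(pulse, "pulse_spec"),
            inherits(background, "background_spec"))
  width <- if (is.null(pulse$width_ms)) 0.25 * frames$T_frame_ms else
    pulse$width_ms
  if (width > frames$T_frame_ms)
    stop("pulse width must satisfy 0 < width <= T_frame")
  structure(list(frames = frames, pulse = pulse, background = background,
                 width_ms = width,
                 span_ms = frames$n_frames * frames$T_frame_ms),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param T_frame_ms,n_frames forwarded to [frame_sequence()].
#' @export
two_pool_schedule <- function(T_frame_ms, n_frames, pulse,
                              background = background_spec()) {
  stimulus_protocol(frame_sequence(T_frame_ms, n_frames), pulse, background)
}

# pulse onset times (ms): one per frame transition
pulse_onsets <- function(protocol) {
  (seq_len(protocol$frames$n_frames) - 1L) * protocol$frames$T_frame_ms
}

#' Decision times of a protocol
#'
#' Times (ms) at which the dominant percept is scored: by default the end of
#' each pulse window, where the activity imbalance is largest and stationary;
#' optionally the pulse midpoint.
#'
#' @param protocol a [stimulus_protocol()].
#' @param at `"pulse_end"` (default) or `"pulse_mid"`.
#' @return Numeric vector of times in ms, one per frame transition.
#' @export
decision_times <- function(protocol, at = c("pulse_end", "pulse_mid")) {
  at <- match.arg(at)
  on <- pulse_onsets(protocol)
  if (at == "pulse_end") on + protocol$width_ms else on + protocol$width_ms / 2
}

# parity before each transition, alternating from start_parity
transition_parities <- function(frames) {
  both <- c("UR-LL", "LR-UL")
  i0 <- match(frames$start_parity, both)
  idx <- (seq_len(frames$n_frames) - 1L + i0 - 1L) %% 2L + 1L
  list(from = both[idx], to = both[3L - idx])
}

# Compile a protocol into the integrator's window representation for a given
# circuit: windows (start, end) in internal time units plus per-window pool
# amplitudes, and the constant background vector / noise sigma.
compile_protocol <- function(protocol, circuit) {
  n <- circuit$n_pools
  mpt <- circuit$ms_per_tau
  on <- pulse_onsets(protocol) / mpt
  w <- protocol$width_ms / mpt
  nf <- protocol$frames$n_frames
  amp <- matrix(0, nf, n)
  if (n == 2L) {
    amp[] <- protocol$pulse$S_on # both pools pulsed each transition
  } else if (identical(circuit$pool_labels, c("V+", "V-", "H+", "H-"))) {
    par <- transition_parities(protocol$frames)
    for (k in seq_len(nf)) {
      driven <- transition_drive(par$from[k], par$to[k])
      amp[k, match(driven, circuit$pool_labels)] <- protocol$pulse$S_on
    }
  } else {
    stop("no pulse mapping for this circuit's pool labels")
  }
  list(windows = cbind(on, on + w), amps = amp,
       bg = rep(protocol$background$S_off, n),
       sigma = protocol$background$sigma,
       seed = protocol$background$seed)
}

#' Drive vector at a given time
#'
#' Evaluates `S_i(t)` for a protocol. In gaussian background mode each call
#' draws fresh noise from R's RNG stream (the integrator itself redraws once
#' per step); seed the stream for reproducibility.
#'
#' @param t_ms time in ms, within `[0, span]` of the protocol.
#' @param protocol a [stimulus_protocol()].
#' @param circuit the circuit the protocol drives (for pool count/labels).
#' @return Length-N drive vector (internal units).
#' @export
drive_at_time <- function(t_ms, protocol, circuit) {
  if (t_ms < 0 || t_ms > protocol$span_ms)
    stop("t outside the protocol span [0, ", protocol$span_ms, "] ms")
  cp <- compile_protocol(protocol, circuit)
  t <- t_ms / circuit$ms_per_tau
  drv <- cp$bg
  if (cp$sigma > 0) drv <- drv + stats::rnorm(length(drv), 0, cp$sigma)
  k <- which(t >= cp$windows[, 1] & t < cp$windows[, 2])
  if (length(k)) drv <- drv + cp$amps[k[1], ]
  drv
}
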