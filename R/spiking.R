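#' Conductance-style spiking two-pool circuit
#'
#' A biologically more detailed counterpart of the reduced two-pool rate
#' model: two mutually inhibiting pools of leaky integrate-and-fire neurons
#' with a calcium-activated spike-frequency-adaptation-like current (each
#' spike increments a slowly decaying outward current — the local fatigue)
#' and short-term depression of the cross-pool inhibitory synapses (the
#' nonlocal fatigue). Pools are deliberately small; dominance statistics are
#' therefore subject to finite-size noise, which shrinks as
#' `neurons_per_pool` grows.
#'
#' Voltage is scaled so rest = 0 and threshold = 1; time is in ms. The
#' stimulus protocol maps pulse amplitude `S_on` and background `S_off` to
#' input currents via `current_gain` (both pools are pulsed at each frame
#' transition, as in the reduced rate model).
#'
#' @param neurons_per_pool neurons per pool.
#' @param tau_m_ms membrane time constant.
#' @param t_ref_ms absolute refractory period.
#' @param tau_adapt_ms decay constant of the adaptation (calcium) current.
#' @param adapt_increment adaptation current increment per spike.
#' @param tau_syn_ms inhibitory synaptic decay constant.
#' @param inhibition peak cross-pool inhibitory coupling.
#' @param release_fraction synaptic resources consumed per spike
#'   (depression), in \[0, 1).
#' @param tau_depress_ms depression recovery constant.
#' @param noise_sd white current-noise amplitude (per sqrt(ms)).
#' @param current_gain input current per unit of protocol drive.
#' @param I_background additional constant background current (added to the
#'   mapped `S_off`).
#' @param dt_ms integration step.
#' @return An object of class `spiking_circuit`.
#' @export
spiking_circuit <- function(neurons_per_pool = 20, tau_m_ms = 10,
                            t_ref_ms = 2, tau_adapt_ms = 4000,
                            adapt_increment = 0.01, tau_syn_ms = 30,
                            inhibition = 25, release_fraction = 0.05,
                            tau_depress_ms = 2000, noise_sd = 0.08,
                            current_gain = 1, I_background = 0.92,
                            dt_ms = 0.1) {
  stopifnot(neurons_per_pool >= 1, tau_m_ms > 0, tau_adapt_ms > 0,
            tau_syn_ms > 0, tau_depress_ms > 0, inhibition >= 0,
            release_fraction >= 0, release_fraction < 1, dt_ms > 0)
  structure(list(
    neurons_per_pool = as.integer(neurons_per_pool), tau_m_ms = tau_m_ms,
    t_ref_ms = t_ref_ms, tau_adapt_ms = tau_adapt_ms,
    adapt_increment = adapt_increment, tau_syn_ms = tau_syn_ms,
    inhibition = inhibition, release_fraction = release_fraction,
    tau_depress_ms = tau_depress_ms, noise_sd = noise_sd,
    current_gain = current_gain, I_background = I_background,
    dt_ms = dt_ms), class = "spiking_circuit")
}

#' @export
print.spiking_circuit <- function(x, ...) {
  cat(sprintf(
    "spiking circuit: 2 pools x %d LIF neurons\n", x$neurons_per_pool))
  cat(sprintf("  adaptation: +%g per spike, tau = %g ms; inhibition J = %g (depression U = %g, tau = %g ms)\n",
              x$adapt_increment, x$tau_adapt_ms, x$inhibition,
              x$release_fraction, x$tau_depress_ms))
  cat(sprintf("  background current = %g, noise sd = %g\n",
              x$I_background, x$noise_sd))
  invisible(x)
}

#' Simulate the spiking circuit under a stimulus protocol
#'
#' @param params a [spiking_circuit()].
#' @param protocol a [stimulus_protocol()]; both pools are pulsed at each
#'   frame transition. Only the fixed/zero background modes are used: the
#'   spiking model has its own intrinsic current noise.
#' @param seed integer seed (initial-condition jitter and current noise).
#' @param t_end_ms simulation end (default: protocol span).
#' @return An object of class `spike_record`: data frame `spikes`
#'   (`time_ms`, `neuron`, `pool`) plus the protocol and parameters.
#' @export
simulate_spiking <- function(params, protocol, seed = 1,
                             t_end_ms = NULL) {
  stopifnot(inherits(params, "spiking_circuit"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(t_end_ms)) t_end_ms <- protocol$span_ms
  on <- pulse_onsets(protocol)
  windows <- cbind(on, on + protocol$width_ms)
  win_pools <- matrix(1L, nrow(windows), 2)
  set.seed(seed)
  res <- .spiking_sim_cpp(
    params$neurons_per_pool, params$tau_m_ms, params$t_ref_ms,
    params$tau_adapt_ms, params$adapt_increment, params$tau_syn_ms,
    params$inhibition, params$release_fraction, params$tau_depress_ms,
    params$noise_sd, params$dt_ms, t_end_ms,
    params$current_gain * protocol$pulse$S_on,
    params$I_background + params$current_gain * protocol$background$S_off,
    windows, win_pools)
  spikes <- data.frame(time_ms = res$time_ms, neuron = as.integer(res$neuron))
  spikes$pool <- ifelse(spikes$neuron <= params$neurons_per_pool, "H", "V")
  structure(list(spikes = spikes, params = params, protocol = protocol,
                 t_end_ms = t_end_ms, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike record: %d spikes over %g ms (%d neurons/pool)\n",
              nrow(x$spikes), x$t_end_ms, x$params$neurons_per_pool))
  invisible(x)
}

#' Pool firing rates on a sliding window
#'
#' @param record a [simulate_spiking()] result.
#' @param times_ms evaluation times.
#' @param window_ms averaging window (spikes in `[t - window, t)`).
#' @return Matrix of per-pool rates in Hz (columns `H`, `V`).
#' @export
pool_rates <- function(record, times_ms, window_ms = 50) {
  M <- record$params$neurons_per_pool
  sp <- record$spikes
  out <- vapply(times_ms, function(t) {
    in_win <- sp$time_ms >= t - window_ms & sp$time_ms < t
    c(sum(in_win & sp$pool == "H"), sum(in_win & sp$pool == "V")) /
      (M * window_ms / 1000)
  }, numeric(2))
  m <- t(out)
  colnames(m) <- c("H", "V")
  m
}

#' Dominance records from a spike record
#'
#' The pool with the higher windowed firing rate at each decision time is
#' dominant; ties retain the previous label (shared tie rule with the rate
#' model readout). The resulting percept trace is run-length encoded by
#' [dominance_records()].
#'
#' @param record a [simulate_spiking()] result.
#' @param decision_times_ms decision times (default: pulse ends).
#' @param window_ms rate window; must be shorter than the frame interval.
#' @return A [dominance_records()] data frame.
#' @export
rates_to_records <- function(record, decision_times_ms = NULL,
                             window_ms = 50) {
  if (window_ms <= 0) stop("empty rate window")
  if (window_ms >= record$protocol$frames$T_frame_ms)
    stop("rate window must be shorter than the frame interval")
  if (is.null(decision_times_ms))
    decision_times_ms <- decision_times(record$protocol)
  r <- pool_rates(record, decision_times_ms, window_ms)
  lab <- character(nrow(r))
  prev <- NA_character_
  for (k in seq_len(nrow(r))) {
    if (max(r[k, ]) == 0) { lab[k] <- "none"; next }
    d <- r[k, 1] - r[k, 2]
    lab[k] <- if (abs(d) < 1e-9) {
      if (is.na(prev)) "H" else prev
    } else if (d > 0) "H" else "V"
    prev <- lab[k]
  }
  trace <- structure(data.frame(time_ms = decision_times_ms, label = lab),
                     class = c("percept_trace", "data.frame"),
                     pool_labels = c("H", "V"))
  dominance_records(trace)
}
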