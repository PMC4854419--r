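#' Construct a mutual-inhibition rate circuit
#'
#' Defines an N-pool canonical cortical circuit. Pool activities `u_i` obey
#' (time rescaled so the activity time constant is 1)
#' \deqn{du_i/dt = -u_i + f(S_i + \sum_j s_{ij} \beta_{ij} u_j - \gamma a_i)}
#' \deqn{\tau_a \, da_i/dt = -a_i + u_i}
#' \deqn{\tau_s \, ds_{ij}/dt = 1 - s_{ij} - \phi s_{ij} u_j}
#' where `f` is the gain, `beta` the signed synaptic weight matrix (negative =
#' inhibition), `a_i` a local fatigue variable (spike-frequency adaptation or
#' within-pool synaptic depression) of strength `gamma`, and `s_ij` a nonlocal
#' fatigue (cross-synaptic depression) variable of strength `phi` applied
#' uniformly to every connection; `phi = 0` disables it.
#'
#' Time at the user interface is in milliseconds; internally time is rescaled
#' so that the activity time constant equals one, with `ms_per_tau`
#' milliseconds per internal unit. Fatigue time constants should be much
#' slower than the activity time constant (seconds vs tens of milliseconds).
#'
#' @param weights signed N x N weight matrix `beta_ij` (entry `[i, j]` is the
#'   connection from pool `j` onto pool `i`).
#' @param local_fatigue local fatigue strength `gamma >= 0`.
#' @param nonlocal_fatigue nonlocal fatigue strength `phi >= 0`.
#' @param tau_a_ms,tau_s_ms fatigue time constants, in ms.
#' @param ms_per_tau milliseconds per activity time constant (conversion
#'   between wall-clock stimulus times and internal model time).
#' @param gain a [gain_function()].
#' @param pool_labels character labels, one per pool.
#' @return An object of class `rivalry_circuit`.
#' @seealso [two_pool_circuit()], [quartet_circuit()], [simulate.rivalry_circuit()]
#' @export
rivalry_circuit <- function(weights, local_fatigue = 0, nonlocal_fatigue = 0,
                            tau_a_ms = 2000, tau_s_ms = 2000,
                            ms_per_tau = 10, gain = gain_function("hard"),
                            pool_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 2L || ncol(weights) != n)
    stop("'weights' must be a square matrix with at least 2 pools")
  if (any(!is.finite(weights))) stop("'weights' must be finite")
  if (local_fatigue < 0 || nonlocal_fatigue < 0)
    stop("fatigue strengths must be non-negative")
  if (tau_a_ms <= 0 || tau_s_ms <= 0 || ms_per_tau <= 0)
    stop("time constants must be positive")
  if (tau_a_ms < 5 * ms_per_tau || tau_s_ms < 5 * ms_per_tau)
    stop("fatigue time constants must be much slower than the activity ",
         "time constant (require tau_a, tau_s >= 5 * ms_per_tau)")
  if (is.null(pool_labels)) pool_labels <- paste0("pool", seq_len(n))
  if (length(pool_labels) != n) stop("need one pool label per pool")
  dimnames(weights) <- list(pool_labels, pool_labels)
  structure(list(
    n_pools = n,
    weights = weights,
    local_fatigue = as.numeric(local_fatigue),
    nonlocal_fatigue = as.numeric(nonlocal_fatigue),
    tau_u = 1,
    tau_a = tau_a_ms / ms_per_tau,
    tau_s = tau_s_ms / ms_per_tau,
    ms_per_tau = as.numeric(ms_per_tau),
    gain = gain,
    pool_labels = pool_labels
  ), class = "rivalry_circuit")
}

#' Reduced two-pool rivalry circuit
#'
#' The quartet circuit averaged over the fast direction oscillations: two
#' mutually inhibiting pools representing horizontal (H) and vertical (V)
#' orientation percepts. Excitation between like-orientation pools is
#' subsumed within each pool; optional recurrent (self) excitation restores
#' it explicitly for the persistent-activity regime.
#'
#' @param inhibition mutual inhibition magnitude (> 0); the off-diagonal
#'   weights are `-inhibition`.
#' @param self_excitation recurrent excitation weight (>= 0, default 0;
#'   persistent-activity regime only).
#' 
#' @param ... passed to [rivalry_circuit()].
#' @return A 2-pool `rivalry_circuit` with labels `H`, `V`.
#' @export
two_pool_circuit <- function(inhibition = 2, self_excitation = 0, ...) {
  if (!is.numeric(inhibition) || length(inhibition) != 1L || inhibition <= 0)
    stop("'inhibition' must be a positive magnitude: the two pools must be ",
         "a mutually inhibiting rivalry pair")
  if (self_excitation < 0) stop("'self_excitation' must be >= 0")
  w <- matrix(c(self_excitation, -inhibition,
                -inhibition, self_excitation), 2, 2)
  rivalry_circuit(w, pool_labels = c("H", "V"), ...)
}

#' Four-pool quartet circuit
#'
#' The minimal circuit for the ambiguous quartet illusion: four pools
#' labelled `V+`, `V-`, `H+`, `H-` (orientation x rotation direction).
#' Competing percept pairs (`V+`/`H-` and `V-`/`H+`, the two interpretations
#' of the same frame transition) are mutually inhibiting; like-orientation
#' pairs (`V+`/`V-`, `H+`/`H-`) and like-direction pairs (`V+`/`H+`,
#' `V-`/`H-`) are positively coupled, biasing the circuit toward orientation
#' persistence with direction oscillation. The weight matrix is invariant
#' under the quartet symmetry group (swapping H with V and + with -).
#'
#' @param inhibition inhibition magnitude between competing pairs (> 0).
#' @param like_orientation excitatory weight between like-orientation pools
#'   (>= 0; zero gives a degenerate quartet, accepted with a warning).
#' @param like_direction excitatory weight between like-direction pools
#'   (>= 0).
#' @param ... passed to [rivalry_circuit()].
#' @return A 4-pool `rivalry_circuit` with labels `V+`, `V-`, `H+`, `H-`.
#' @export
quartet_circuit <- function(inhibition = 2, like_orientation = 0.4,
                            like_direction = 0.1, ...) {
  if (!is.numeric(inhibition) || length(inhibition) != 1L || inhibition <= 0)
    stop("'inhibition' between competing pairs must be positive")
  if (like_orientation < 0 || like_direction < 0)
    stop("like-orientation and like-direction weights must be non-negative ",
         "(excitatory)")
  if (like_orientation == 0 && like_direction == 0)
    warning("zero like-pair weights: degenerate quartet with no orientation/",
            "direction bias")
  lab <- c("V+", "V-", "H+", "H-")
  w <- matrix(0, 4, 4, dimnames = list(lab, lab))
  w["V+", "H-"] <- w["H-", "V+"] <- -inhibition
  w["V-", "H+"] <- w["H+", "V-"] <- -inhibition
  w["V+", "V-"] <- w["V-", "V+"] <- like_orientation
  w["H+", "H-"] <- w["H-", "H+"] <- like_orientation
  w["V+", "H+"] <- w["H+", "V+"] <- like_direction
  w["V-", "H-"] <- w["H-", "V-"] <- like_direction
  rivalry_circuit(w, pool_labels = lab, ...)
}

#' @export
print.rivalry_circuit <- function(x, ...) {
  cat(sprintf("rivalry circuit: %d pools (%s)\n", x$n_pools,
              paste(x$pool_labels, collapse = ", ")))
  cat(sprintf("  local fatigue gamma = %g (tau_a = %g ms), nonlocal phi = %g (tau_s = %g ms)\n",
              x$local_fatigue, x$tau_a * x$ms_per_tau,
              x$nonlocal_fatigue, x$tau_s * x$ms_per_tau))
  cat(sprintf("  activity time constant = %g ms; gain: %s\n", x$ms_per_tau,
              x$gain$variant))
  cat("  weights beta_ij (j -> i):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Rested circuit state
#'
#' Activities and local fatigue at zero, nonlocal fatigue (synaptic strength
#' scaling) at one.
#'
#' @param circuit a `rivalry_circuit`.
#' @return A `circuit_state` list with elements `u`, `a` (length-N vectors)
#'   and `s` (N x N matrix).
#' @export
rested_state <- function(circuit) {
  n <- circuit$n_pools
  circuit_state(rep(0, n), rep(0, n), matrix(1, n, n))
}

#' @rdname rested_state
#' @param u,a non-negative length-N vectors of activity and local fatigue.
#' @param s N x N nonlocal fatigue matrix with entries in (0, 1].
#' @export
circuit_state <- function(u, a, s) {
  u <- as.numeric(u); a <- as.numeric(a); s <- as.matrix(s)
  n <- length(u)
  if (length(a) != n || nrow(s) != n || ncol(s) != n)
    stop("state dimensions are inconsistent")
  if (any(u < 0) || any(a < 0)) stop("u and a must be non-negative")
  if (any(s <= 0) || any(s > 1)) stop("s entries must lie in (0, 1]")
  structure(list(u = u, a = a, s = s), class = "circuit_state")
}

#' Time derivatives of the rate model
#'
#' Right-hand side of the circuit equations at a given state and drive.
#' Mainly useful for analysis (Jacobians, fixed-point residuals); simulation
#' goes through the compiled integrator in [simulate.rivalry_circuit()].
#'
#' @param state a [circuit_state()].
#' @param drive length-N vector of effective inputs `S_i` (internal units).
#' @param circuit a `rivalry_circuit`.
#' @return List with `du`, `da` (vectors) and `ds` (matrix).
#' @export
circuit_derivatives <- function(state, drive, circuit) {
  n <- circuit$n_pools
  if (length(state$u) != n || length(drive) != n)
    stop("dimension mismatch between state/drive and circuit")
  arg <- drive - circuit$local_fatigue * state$a +
    as.numeric((circuit$weights * state$s) %*% state$u)
  du <- (-state$u + gain_eval(circuit$gain, arg)) / circuit$tau_u
  da <- (-state$a + state$u) / circuit$tau_a
  ds <- (1 - state$s - circuit$nonlocal_fatigue *
           state$s * matrix(state$u, n, n, byrow = TRUE)) / circuit$tau_s
  list(du = du, da = da, ds = ds)
}
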