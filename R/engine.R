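# R-facing wrappers around the compiled DPD core.

engine_par_list <- function(state, params, thermostat = TRUE) {
  list(gamma = if (thermostat) params$gamma else 0,
       sigma = if (thermostat) params$sigma else 0,
       dt = params$dt, kappa = params$kappa, req = params$r_eq,
       awall = params$A_wall, zc = params$z_c,
       walled_x = identical(state$boundary, "walled_x"))
}

species_index <- function(state, matrix) {
  lab <- rownames(matrix)
  idx <- match(state$species, lab)
  if (anyNA(idx))
    stop("species not in interaction matrix: ",
         paste(unique(state$species[is.na(idx)]), collapse = ", "))
  idx
}

#' Evaluate all forces on a state
#'
#' Computes the full DPD force breakdown at the current positions and
#' velocities: soft conservative repulsion F^C = A_ij (1 - r/r_c) rhat, the
#' dissipative drag F^D = -gamma w_D(r) (rhat . v_ij) rhat, the random kick
#' F^R = sigma w_R(r) zeta_ij dt^(-1/2) rhat with w_D = w_R^2 = (1 - r/r_c)^2
#' and one Gaussian variate zeta_ij shared per pair, plus harmonic bond forces
#' and (for walled boxes) the quadratic wall repulsion.  All pair terms are
#' applied antisymmetrically.
#'
#' @param state a [dpd_state()].
#' @param matrix an [build_interaction_matrix()] result.
#' @param params a [dpd_params()] object.
#' @param seed integer seed for the random-force draws.
#' @param thermostat if `FALSE`, dissipative and random forces are switched
#'   off (conservative dynamics).
#' @return List of N x 3 matrices `total`, `conservative`, `dissipative`,
#'   `random`, `bond`, `wall`, plus the scalar conservative virial.
#' @export
compute_forces <- function(state, matrix, params = dpd_params(), seed = params$seed,
                           thermostat = TRUE) {
  cpp_forces(state$positions, state$velocities,
             as.integer(species_index(state, matrix)),
             as.integer(state$frozen), unclass(matrix)[, , drop = FALSE],
             state$bonds, state$box,
             engine_par_list(state, params, thermostat), as.integer(seed))
}

#' Run a DPD simulation
#'
#' Integrates the system with the Groot-Warren modified velocity-Verlet
#' scheme (lambda = 0.5) in the NVT ensemble.  The dissipative/random pair
#' forces form the thermostat; switching them off (`thermostat = FALSE`)
#' yields conservative dynamics, useful for symplectic checks.  Identical
#' seeds give bit-identical trajectories.
#'
#' @inheritParams compute_forces
#' @param steps number of time steps (0 returns the initial state only).
#' @param stride snapshot interval in steps; 0 stores only the initial state.
#' @param seed integer seed for the thermostat noise.
#' @param tethers optional list with `index` (bead indices), `anchor`
#'   (matching k x 3 matrix of anchor points) and `k` (spring constant):
#'   harmonic restraints used by the relaxation stage.
#' @param thermostat logical; include dissipative/random forces.
#' @return A `dpd_trajectory`: the final `state`, snapshot list, per-step
#'   `temperature`, `momentum` and conservative `virial` series, and the run
#'   metadata.
#' @export
run_dpd <- function(state, matrix, params = dpd_params(), steps, stride = 0,
                    seed = params$seed, tethers = NULL, thermostat = TRUE) {
  stopifnot(steps >= 0, stride >= 0)
  if (is.null(tethers)) {
    t_idx <- integer(0); t_anchor <- matrix(0, 0, 3); t_k <- 0
  } else {
    t_idx <- as.integer(tethers$index)
    t_anchor <- as.matrix(tethers$anchor)
    t_k <- tethers$k
    stopifnot(nrow(t_anchor) == length(t_idx), ncol(t_anchor) == 3, t_k >= 0)
  }
  if (steps == 0) {
    return(structure(list(
      state = state, snapshots = list(state$positions),
      snapshot_velocities = list(state$velocities),
      snapshot_steps = 0L, times = 0,
      temperature = numeric(0), momentum = matrix(0, 0, 3),
      virial = numeric(0), params = params, steps = 0L,
      wall_clamped = 0L), class = "dpd_trajectory"))
  }
  res <- cpp_run_dpd(state$positions, state$velocities,
                     as.integer(species_index(state, matrix)),
                     as.integer(state$frozen),
                     unclass(matrix)[, , drop = FALSE], state$bonds,
                     state$box, engine_par_list(state, params, thermostat),
                     as.integer(steps), as.integer(stride), as.integer(seed),
                     t_idx, t_anchor, t_k)
  out <- state
  out$positions <- res$positions
  out$velocities <- res$velocities
  structure(list(
    state = out, snapshots = res$snap_pos,
    snapshot_velocities = res$snap_vel,
    snapshot_steps = res$snap_step,
    times = res$snap_step * params$dt,
    temperature = res$temperature, momentum = res$momentum,
    virial = res$virial_conservative,
    params = params, steps = as.integer(steps),
    wall_clamped = res$wall_clamped), class = "dpd_trajectory")
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf("<dpd_trajectory> %d steps, %d snapshots, %d beads\n",
              x$steps, length(x$snapshots), nrow(x$state$positions)))
  if (length(x$temperature) > 0)
    cat(sprintf("  final kinetic T = %.4f\n", tail(x$temperature, 1)))
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj a `dpd_trajectory`.
#' @export
n_snapshots <- function(traj) length(traj$snapshots)

#' Extract one snapshot as a full state
#'
#' @param traj a `dpd_trajectory` from [run_dpd()].
#' @param i snapshot index (1-based).
#' @return A `dpd_state` with the stored positions and velocities.
#' @export
get_snapshot <- function(traj, i) {
  stopifnot(i >= 1, i <= length(traj$snapshots))
  st <- traj$state
  st$positions <- traj$snapshots[[i]]
  st$velocities <- traj$snapshot_velocities[[i]]
  st
}

#' Virial pressure of a trajectory segment
#'
#' p = rho_free k_B T + W_C / (3 V), with W_C the conservative pair virial,
#' averaged over the second half of the run (or the window given).  For a
#' single-species soft fluid this is the quantity compared against the
#' Groot-Warren equation-of-state estimate p ~ rho kT + 0.101 A rho^2.
#'
#' @param traj a `dpd_trajectory`.
#' @param from first step of the averaging window (default: midpoint).
#' @return Scalar pressure in reduced units.
#' @export
measure_pressure <- function(traj, from = NULL) {
  ns <- length(traj$virial)
  if (ns == 0) stop("trajectory carries no virial series")
  if (is.null(from)) from <- floor(ns / 2) + 1
  win <- from:ns
  V <- prod(traj$state$box)
  nfree <- sum(!traj$state$frozen)
  kT_meas <- mean(traj$temperature[win])
  nfree / V * kT_meas + mean(traj$virial[win]) / (3 * V)
}
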