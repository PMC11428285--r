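#' Construct a DPD system state
#'
#' A `dpd_state` holds everything the integrator needs: bead coordinates and
#' velocities, species labels, molecule membership, the bond list, the box and
#' its boundary mode.  Boxes are periodic in y and z always; in x they are
#' either periodic (`"periodic"`) or bounded by repulsive walls plus frozen
#' bead rows (`"walled_x"`, used for dissolution runs).
#'
#' @param positions N x 3 numeric matrix (reduced length units).
#' @param species character vector of N bead species labels.
#' @param box numeric length-3 box edge lengths (Lx, Ly, Lz).
#' @param velocities N x 3 matrix; defaults to all zero.
#' @param molecule_id integer vector of N molecule ids (1-based, contiguous);
#'   defaults to one molecule per bead.
#' @param molecule_name character vector of N template names per bead;
#'   defaults to the species label.
#' @param bonds m x 2 integer matrix of bead index pairs (may be empty).
#' @param frozen logical vector of N; frozen beads are excluded from
#'   integration (used for wall rows).
#' @param boundary `"periodic"` or `"walled_x"`.
#' @return An object of class `dpd_state`.
#' @export
dpd_state <- function(positions, species, box, velocities = NULL,
                      molecule_id = NULL, molecule_name = NULL,
                      bonds = NULL, frozen = NULL,
                      boundary = c("periodic", "walled_x")) {
  boundary <- match.arg(boundary)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(species) == n, length(box) == 3,
            all(box > 0))
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(molecule_id)) molecule_id <- seq_len(n)
  if (is.null(molecule_name)) molecule_name <- as.character(species)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  stopifnot(nrow(velocities) == n, length(molecule_id) == n,
            length(frozen) == n, length(molecule_name) == n)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n))
    stop("bond indices out of range")
  st <- structure(list(
    positions = unname(positions), velocities = unname(as.matrix(velocities)),
    species = as.character(species), molecule_id = as.integer(molecule_id),
    molecule_name = as.character(molecule_name),
    bonds = bonds, frozen = as.logical(frozen),
    box = as.numeric(box), boundary = boundary), class = "dpd_state")
  wrap_state(st)
}

#' @export
print.dpd_state <- function(x, ...) {
  cat(sprintf("<dpd_state> %d beads (%d frozen), box %g x %g x %g, %s\n",
              nrow(x$positions), sum(x$frozen),
              x$box[1], x$box[2], x$box[3], x$boundary))
  tab <- table(x$species)
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = " "),
      sprintf("| %d bonds\n", nrow(x$bonds)))
  invisible(x)
}

n_beads <- function(state) nrow(state$positions)

#' @rdname dpd_state
#' @param state a `dpd_state`.
#' @export
n_free_beads <- function(state) sum(!state$frozen)

# wrap coordinates into the box in the periodic directions
wrap_state <- function(state) {
  p <- state$positions
  dims <- if (state$boundary == "walled_x") 2:3 else 1:3
  for (d in dims) {
    L <- state$box[d]
    p[, d] <- p[, d] - L * floor(p[, d] / L)
    p[p[, d] >= L, d] <- 0
  }
  state$positions <- p
  state
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns thermal velocities at temperature `kT` to all free beads (frozen
#' beads stay at rest) and removes the centre-of-mass drift of the free set.
#'
#' @param state a `dpd_state`.
#' @param kT temperature in reduced units.
#' @param seed integer seed.
#' @return The state with new velocities.
#' @export
thermalize <- function(state, kT = 1, seed = 1L) {
  n <- n_beads(state)
  free <- !state$frozen
  set.seed(as.integer(seed))
  v <- matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3)
  v[!free, ] <- 0
  if (sum(free) > 1) {
    com <- colMeans(v[free, , drop = FALSE])
    v[free, ] <- sweep(v[free, , drop = FALSE], 2, com)
  }
  state$velocities <- v
  state
}

#' Kinetic temperature of a state
#'
#' Mean kinetic energy per free bead times 2/3, in reduced units
#' (equipartition with m = 1).
#'
#' @param state a `dpd_state` with at least 2 free beads.
#' @return Scalar temperature.
#' @export
measure_temperature <- function(state) {
  free <- !state$frozen
  if (sum(free) < 2) stop("temperature undefined: fewer than 2 free beads")
  v <- state$velocities[free, , drop = FALSE]
  sum(v^2) / (3 * sum(free))
}

#' Total momentum of the free beads
#'
#' @param state a `dpd_state`.
#' @return Numeric length-3 momentum vector (m = 1).
#' @export
total_momentum <- function(state) {
  free <- !state$frozen
  colSums(state$velocities[free, , drop = FALSE])
}
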