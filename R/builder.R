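# Construction of the two-stage dissolution experiment: random mixed box ->
# equilibrated lamellar phase -> rotate/crop -> stitch to water behind walls
# -> restrained relaxation.

#' Composition specification for a simulation box
#'
#' Volume fractions are bookkept as bead-count fractions (all beads have unit
#' volume in the coarse-grained model), so a fraction f of molecule m means
#' f * rho * V beads belong to molecules of that template.
#'
#' @param fractions named numeric vector of volume fractions per molecule
#'   template name; must sum to 1.
#' @param box numeric length-3 box dimensions.
#' @param rho target bead density (default 3).
#' @return A `composition_spec` object.
#' @export
composition_spec <- function(fractions, box, rho = 3) {
  stopifnot(length(box) == 3, all(box > 0), rho > 0,
            !is.null(names(fractions)), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  structure(list(fractions = fractions, box = as.numeric(box), rho = rho),
            class = "composition_spec")
}

# Largest-remainder allocation of N beads to molecule templates.
# Returns integer molecule counts per template.
allocate_molecules <- function(fractions, sizes, n_beads) {
  quota <- fractions * n_beads / sizes      # ideal molecule counts
  n_mol <- floor(quota)
  rem_beads <- n_beads - sum(n_mol * sizes)
  # hand out whole molecules by largest remainder while they fit
  ord <- order(quota - n_mol, decreasing = TRUE)
  for (i in ord) {
    if (sizes[i] <= rem_beads && (quota[i] - n_mol[i]) > 0) {
      n_mol[i] <- n_mol[i] + 1
      rem_beads <- rem_beads - sizes[i]
    }
  }
  # any leftover beads go to single-bead templates (water) if present
  ones <- which(sizes == 1)
  if (rem_beads > 0 && length(ones) > 0) {
    n_mol[ones[1]] <- n_mol[ones[1]] + rem_beads
    rem_beads <- 0
  }
  attr(n_mol, "unallocated_beads") <- rem_beads
  n_mol
}

#' Build a randomly mixed box at target density
#'
#' Places whole molecules as random-walk chains (step length = the bond
#' equilibrium length) until N = round(rho * V) beads are reached, with
#' molecule counts allocated to the requested volume fractions by
#' largest-remainder rounding.  Velocities are drawn at kT = 1.
#'
#' @param spec a [composition_spec()].
#' @param templates list of [build_molecule_templates()] entries covering all
#'   names in `spec$fractions`.
#' @param seed integer seed.
#' @param kT temperature for the initial velocities.
#' @param arrange `"random"` (default) scatters molecules as random-walk
#'   coils; `"layered"` seeds bonded amphiphiles in alternating bilayer
#'   leaflets stacked along x (tails toward the mid-planes), which shortens
#'   the equilibration of high-concentration lamellar boxes.  An unstable
#'   seeded stack melts during equilibration, so the arrangement biases the
#'   starting point, not the verdict of the structure-factor check.
#' @param n_layers number of bilayers for `arrange = "layered"` (default:
#'   one per 5 r_c of box length).
#' @return A periodic `dpd_state`.
#' @export
build_random_box <- function(spec, templates, seed = 1L, kT = 1,
                             arrange = c("random", "layered"),
                             n_layers = NULL) {
  arrange <- match.arg(arrange)
  stopifnot(inherits(spec, "composition_spec"))
  miss <- setdiff(names(spec$fractions), names(templates))
  if (length(miss) > 0)
    stop("no template for molecule(s): ", paste(miss, collapse = ", "))
  V <- prod(spec$box)
  N <- round(spec$rho * V)
  fr <- spec$fractions[spec$fractions > 0]
  sizes <- vapply(names(fr), function(nm) length(templates[[nm]]$beads), 1L)
  n_mol <- allocate_molecules(fr, sizes, N)
  if (any(n_mol == 0 & fr > 0))
    stop("fraction of '", names(fr)[which(n_mol == 0 & fr > 0)[1]],
         "' yields less than one molecule in this box")
  set.seed(as.integer(seed))
  if (is.null(n_layers)) n_layers <- max(1L, round(spec$box[1] / 5))
  period <- spec$box[1] / n_layers
  total_beads <- sum(n_mol * sizes)
  pos <- matrix(0, total_beads, 3)
  species <- character(total_beads)
  mol_id <- integer(total_beads)
  mol_name <- character(total_beads)
  bonds <- vector("list", sum(n_mol))
  at <- 0L; mol <- 0L
  for (i in seq_along(fr)) {
    tmpl <- templates[[names(fr)[i]]]
    nb <- length(tmpl$beads)
    layered <- arrange == "layered" && nb > 1
    for (k in seq_len(n_mol[i])) {
      mol <- mol + 1L
      p <- matrix(0, nb, 3)
      if (layered) {
        # leaflet of a bilayer: first (tail) bead near a mid-plane, chain
        # walking outward along +/- x with transverse jitter
        plane <- (sample.int(n_layers, 1) - 0.5) * period
        side <- sample(c(-1, 1), 1)
        p[1, ] <- c(plane + side * 0.1 * runif(1),
                    runif(2) * spec$box[2:3])
        if (nb > 1) {
          dirs <- cbind(side * abs(rnorm(nb - 1, 1, 0.3)),
                        rnorm(nb - 1, 0, 0.45), rnorm(nb - 1, 0, 0.45))
          dirs <- dirs / sqrt(rowSums(dirs^2))
          p[-1, ] <- dirs * tmpl$r_eq
          p <- apply(p, 2, cumsum)
        }
      } else {
        p[1, ] <- runif(3) * spec$box
        if (nb > 1) {
          # random walk with fixed step = r_eq
          dirs <- matrix(rnorm(3 * (nb - 1)), nb - 1, 3)
          dirs <- dirs / sqrt(rowSums(dirs^2))
          p[-1, ] <- dirs * tmpl$r_eq
          p <- apply(p, 2, cumsum)
        }
      }
      idx <- at + seq_len(nb)
      pos[idx, ] <- p
      species[idx] <- tmpl$beads
      mol_id[idx] <- mol
      mol_name[idx] <- tmpl$name
      if (nrow(tmpl$bonds) > 0) bonds[[mol]] <- tmpl$bonds + at
      at <- at + nb
    }
  }
  bonds <- do.call(rbind, bonds[!vapply(bonds, is.null, TRUE)])
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  st <- dpd_state(pos, species, spec$box, molecule_id = mol_id,
                  molecule_name = mol_name, bonds = bonds,
                  boundary = "periodic")
  thermalize(st, kT = kT, seed = seed + 1L)
}

amphiphile_mask <- function(state) {
  !(state$species %in% c("W")) & !state$frozen
}

#' One-dimensional structure factor of the hydrophobic-bead density
#'
#' Normalized structure factor |sum exp(i k x)|^2 / N^2 for wavevectors
#' k_n = 2 pi n / L along each axis.  By default it is computed over the
#' hydrophobic tail beads (species A): at high surfactant concentration the
#' total amphiphile density is nearly uniform and carries almost no layering
#' signal, while the tail density alternates strongly between bilayer cores
#' and head/water galleries.  A lamellar phase peaks at the layer-stacking
#' mode along its normal; a disordered fluid stays at O(1/N).
#'
#' @param state a `dpd_state`.
#' @param species_set bead species whose density is transformed (default
#'   `"A"`).
#' @param n_max largest mode number per axis (default 6).
#' @return A data.frame with columns `axis`, `mode`, `s` (normalized).
#' @export
structure_factor <- function(state, species_set = "A", n_max = 6) {
  sel <- state$species %in% species_set & !state$frozen
  if (!any(sel)) stop("no beads of the requested species in state")
  p <- state$positions[sel, , drop = FALSE]
  N <- nrow(p)
  out <- expand.grid(axis = 1:3, mode = seq_len(n_max))
  out$s <- mapply(function(ax, n) {
    phase <- 2 * pi * n * p[, ax] / state$box[ax]
    (sum(cos(phase))^2 + sum(sin(phase))^2) / N^2
  }, out$axis, out$mode)
  out
}

#' Radially binned structure factor of a bead species
#'
#' Averages the normalized structure factor over all integer wavevectors
#' n = (n1, n2, n3) with the same rounded modulus, up to `n_max`.  A
#' microphase-separated system (lamellar layering included, whatever its
#' orientation) shows a pronounced peak at the domain-spacing shell
#' |k| = 2 pi |n*| / L, while a disordered fluid decays monotonically at the
#' O(1/N) noise floor.  This is the orientation-free companion of
#' [structure_factor()]: small boxes develop the density wave long before the
#' layer normal anneals onto a single axis.
#'
#' @inheritParams structure_factor
#' @param n_max largest |n| shell (default 6).
#' @return data.frame with `shell` (|n| rounded), `k` (2 pi shell / L for a
#'   cubic box), `s` (mean normalized intensity over the shell).
#' @export
structure_factor_radial <- function(state, species_set = "A", n_max = 6) {
  sel <- state$species %in% species_set & !state$frozen
  if (!any(sel)) stop("no beads of the requested species in state")
  p <- state$positions[sel, , drop = FALSE]
  N <- nrow(p)
  L <- state$box
  grid <- expand.grid(n1 = 0:n_max, n2 = -n_max:n_max, n3 = -n_max:n_max)
  # half space, origin removed (conjugate symmetry)
  grid <- grid[!(grid$n1 == 0 & (grid$n2 < 0 | (grid$n2 == 0 & grid$n3 <= 0))), ]
  nn <- sqrt(grid$n1^2 + grid$n2^2 + grid$n3^2)
  grid <- grid[nn <= n_max, ]
  nn <- nn[nn <= n_max]
  kx <- 2 * pi * grid$n1 / L[1]
  ky <- 2 * pi * grid$n2 / L[2]
  kz <- 2 * pi * grid$n3 / L[3]
  s <- vapply(seq_len(nrow(grid)), function(i) {
    ph <- p[, 1] * kx[i] + p[, 2] * ky[i] + p[, 3] * kz[i]
    (sum(cos(ph))^2 + sum(sin(ph))^2) / N^2
  }, 1.0)
  shell <- round(nn)
  out <- data.frame(shell = sort(unique(shell)))
  out$k <- 2 * pi * out$shell / mean(L)
  out$s <- vapply(out$shell, function(sh) mean(s[shell == sh]), 1.0)
  out
}

#' Detect a microphase-separation density wave
#'
#' `TRUE` when the radial structure factor of the tail beads has an interior
#' peak whose intensity exceeds `threshold` -- evidence of a periodic
#' surfactant density wave of any orientation.
#'
#' @inheritParams structure_factor_radial
#' @param threshold intensity threshold on the shell-averaged peak (default
#'   0.005; the disordered-fluid floor is O(1/N), about 1e-3 at a few
#'   thousand beads).
#' @return List with `detected`, `shell`, `spacing` (box length / shell) and
#'   `strength`.
#' @export
detect_density_wave <- function(state, species_set = "A", n_max = 6,
                                threshold = 0.005) {
  sf <- structure_factor_radial(state, species_set, n_max)
  i <- which.max(sf$s)
  list(detected = sf$s[i] >= threshold, shell = sf$shell[i],
       spacing = mean(state$box) / sf$shell[i], strength = sf$s[i])
}

#' Detect the lamellar layer normal
#'
#' Finds the dominant amphiphile density wave over the three axes.  The phase
#' is called lamellar when the strongest normalized structure-factor peak
#' exceeds `threshold` (default 0.04; a disordered fluid sits around 1/N).
#'
#' @inheritParams structure_factor
#' @param threshold detection threshold on the normalized peak.
#' @return List with `axis`, `mode` (number of layer periods along the axis),
#'   `strength`, `lamellar` (logical).
#' @export
detect_lamellar_normal <- function(state, species_set = "A", n_max = 6,
                                   threshold = 0.04) {
  sf <- structure_factor(state, species_set, n_max)
  best <- sf[which.max(sf$s), ]
  list(axis = best$axis, mode = best$mode, strength = best$s,
       lamellar = best$s >= threshold)
}

#' Equilibrate a box towards its mesophase
#'
#' Runs the DPD dynamics in chunks, tracking the dominant structure-factor
#' peak, and stops when the peak has plateaued (relative change below
#' `plateau_tol` across `window` consecutive chunks) or `max_steps` is
#' reached.
#'
#' @param state periodic `dpd_state`.
#' @param matrix interaction matrix.
#' @param params [dpd_params()].
#' @param max_steps hard cap on steps.
#' @param chunk steps per monitoring chunk.
#' @param window number of consecutive chunks for the plateau criterion.
#' @param plateau_tol relative change threshold.
#' @param seed integer seed.
#' @return A list: final `state`, `history` data.frame (step, peak strength),
#'   `converged` flag.
#' @export
equilibrate_lamellar <- function(state, matrix, params = dpd_params(),
                                 max_steps = 40000, chunk = 2000, window = 3,
                                 plateau_tol = 0.1, seed = params$seed) {
  steps_done <- 0
  hist_step <- numeric(0); hist_peak <- numeric(0)
  converged <- FALSE
  while (steps_done < max_steps) {
    n <- min(chunk, max_steps - steps_done)
    traj <- run_dpd(state, matrix, params, steps = n, stride = 0,
                    seed = seed + steps_done)
    state <- traj$state
    steps_done <- steps_done + n
    det <- detect_lamellar_normal(state)
    hist_step <- c(hist_step, steps_done)
    hist_peak <- c(hist_peak, det$strength)
    k <- length(hist_peak)
    if (k > window && det$lamellar) {
      recent <- hist_peak[(k - window):k]
      if (max(abs(diff(recent))) / max(recent) < plateau_tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(state = state, history = data.frame(step = hist_step, peak = hist_peak),
       converged = converged)
}

# unwrap each molecule so it is contiguous relative to its first bead
unwrap_molecules <- function(state) {
  p <- state$positions
  L <- state$box
  per <- if (state$boundary == "walled_x") c(FALSE, TRUE, TRUE) else rep(TRUE, 3)
  ord <- order(state$molecule_id, seq_len(nrow(p)))
  # beads of a molecule are stored consecutively by construction; walk bonds
  # is overkill -- use consecutive-bead differences within each molecule
  for (m in split(ord, state$molecule_id[ord])) {
    if (length(m) < 2) next
    for (j in 2:length(m)) {
      d <- p[m[j], ] - p[m[j - 1], ]
      for (dd in 1:3) {
        if (per[dd]) {
          if (d[dd] > L[dd] / 2) d[dd] <- d[dd] - L[dd]
          if (d[dd] < -L[dd] / 2) d[dd] <- d[dd] + L[dd]
        }
      }
      p[m[j], ] <- p[m[j - 1], ] + d
    }
  }
  state$positions <- p
  state
}

#' Rotate a lamellar box so the layer normal is x, and crop layers
#'
#' Detects the lamellar normal by the structure-factor criterion, permutes the
#' coordinate axes so the normal lies along x, and crops the box to
#' `n_layers` layer periods.  Molecules are kept whole: a molecule belongs to
#' the crop iff its first bead falls inside it.
#'
#' @param state equilibrated periodic `dpd_state` containing a lamellar phase.
#' @param n_layers number of layer periods to keep (default 4).
#' @param threshold lamellar detection threshold passed to
#'   [detect_lamellar_normal()].
#' @return A periodic `dpd_state` with box (n_layers * period, Ly, Lz).
#' @export
crop_and_rotate <- function(state, n_layers = 4, threshold = 0.04) {
  det <- detect_lamellar_normal(state, threshold = threshold)
  if (!det$lamellar)
    stop("not lamellar: no periodic density wave detected (peak ",
         signif(det$strength, 3), " < ", threshold, ")")
  # permute axes so the normal axis becomes x
  perm <- switch(det$axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  state$positions <- state$positions[, perm, drop = FALSE]
  state$box <- state$box[perm]
  if (det$mode < n_layers)
    stop("not lamellar: only ", det$mode, " layer period(s) along the normal, ",
         n_layers, " requested")
  period <- state$box[1] / det$mode
  keep_len <- n_layers * period
  state <- unwrap_molecules(state)
  first <- !duplicated(state$molecule_id)
  first_x <- state$positions[first, 1][state$molecule_id]
  first_x <- first_x - state$box[1] * floor(first_x / state$box[1])
  keep <- first_x < keep_len
  subset_state(state, keep, new_box = c(keep_len, state$box[2], state$box[3]))
}

# keep the selected beads, renumber molecules, remap bonds
subset_state <- function(state, keep, new_box = NULL) {
  idx <- which(keep)
  map <- integer(n_beads(state))
  map[idx] <- seq_along(idx)
  b <- state$bonds
  if (nrow(b) > 0) {
    kb <- keep[b[, 1]] & keep[b[, 2]]
    b <- matrix(map[b[kb, , drop = FALSE]], ncol = 2)
  }
  old_mol <- state$molecule_id[idx]
  st <- state
  st$positions <- state$positions[idx, , drop = FALSE]
  st$velocities <- state$velocities[idx, , drop = FALSE]
  st$species <- state$species[idx]
  st$molecule_id <- as.integer(factor(old_mol, levels = unique(old_mol)))
  st$molecule_name <- state$molecule_name[idx]
  st$frozen <- state$frozen[idx]
  st$bonds <- b
  if (!is.null(new_box)) st$box <- new_box
  wrap_state(st)
}

# two square-lattice rows of frozen W beads near an x position
make_wall_rows <- function(x0, direction, Ly, Lz, spacing = 0.7) {
  ny <- max(1, round(Ly / spacing)); nz <- max(1, round(Lz / spacing))
  ys <- (seq_len(ny) - 0.5) * Ly / ny
  zs <- (seq_len(nz) - 0.5) * Lz / nz
  g <- expand.grid(y = ys, z = zs)
  row_dx <- 0.5 * direction
  rbind(cbind(x0, g$y, g$z), cbind(x0 + row_dx, g$y + Ly / (2 * ny), g$z + Lz / (2 * nz)))
}

#' Stitch a lamellar slab to a water column behind fixed walls
#'
#' Builds the dissolution initial condition: the lamellar slab is placed at
#' the low-x end of a longer box whose total length is chosen so that the
#' overall amphiphile concentration equals `end_conc` (default 20 vol%); the
#' remainder is filled with water at the same density, briefly
#' pre-equilibrated.  Both x ends are closed by the quadratic wall repulsion
#' plus two rows of frozen W beads.
#'
#' @param lamellar a periodic `dpd_state` (output of [crop_and_rotate()]).
#' @param matrix interaction matrix (for the water pre-equilibration).
#' @param params [dpd_params()].
#' @param end_conc target overall amphiphile volume fraction (default 0.2).
#' @param water_equil_steps steps of pre-equilibration of the water column.
#' @param seed integer seed.
#' @return A `dpd_state` with `boundary = "walled_x"`.
#' @export
stitch_dissolution_box <- function(lamellar, matrix, params = dpd_params(),
                                   end_conc = 0.2, water_equil_steps = 200,
                                   seed = 1L) {
  L <- lamellar$box
  # molecules wrapped across the periodic x-boundary must be made contiguous
  # before x becomes walled; molecules dipping below x = 0 take the image on
  # the high side (they may protrude into the water region, which the
  # restrained relaxation evens out)
  lamellar <- unwrap_molecules(lamellar)
  minx <- tapply(lamellar$positions[, 1], lamellar$molecule_id, min)
  shift <- L[1] * ceiling(pmax(0, -minx[as.character(lamellar$molecule_id)]) / L[1])
  lamellar$positions[, 1] <- lamellar$positions[, 1] + shift
  n_amph <- sum(amphiphile_mask(lamellar))
  conc0 <- n_amph / (params$rho * prod(L))
  if (conc0 <= end_conc)
    stop("lamellar box concentration (", signif(conc0, 3),
         ") must exceed the end concentration (", end_conc, ")")
  total_len <- conc0 * L[1] / end_conc
  water_len <- total_len - L[1]
  wspec <- composition_spec(c(water = 1), c(water_len, L[2], L[3]),
                            rho = params$rho)
  wtempl <- build_molecule_templates("water", kappa = params$kappa,
                                     r_eq = params$r_eq)
  water <- build_random_box(wspec, wtempl, seed = seed)
  if (water_equil_steps > 0)
    water <- run_dpd(water, matrix, params, steps = water_equil_steps,
                     seed = seed + 7L)$state
  # shift water to the right of the lamellar slab
  water$positions[, 1] <- water$positions[, 1] + L[1]
  n1 <- n_beads(lamellar)
  wall_lo <- make_wall_rows(0.05, +1, L[2], L[3])
  wall_hi <- make_wall_rows(total_len - 0.05, -1, L[2], L[3])
  walls <- rbind(wall_lo, wall_hi)
  nw <- nrow(walls)
  pos <- rbind(lamellar$positions, water$positions, walls)
  vel <- rbind(lamellar$velocities, water$velocities, matrix(0, nw, 3))
  mol_off <- max(lamellar$molecule_id)
  mol_id <- c(lamellar$molecule_id, water$molecule_id + mol_off,
              max(water$molecule_id) + mol_off + seq_len(nw))
  st <- dpd_state(
    positions = pos,
    species = c(lamellar$species, water$species, rep("W", nw)),
    box = c(total_len, L[2], L[3]),
    velocities = vel,
    molecule_id = mol_id,
    molecule_name = c(lamellar$molecule_name, water$molecule_name,
                      rep("wall", nw)),
    bonds = rbind(lamellar$bonds, water$bonds + n1),
    frozen = c(lamellar$frozen, water$frozen, rep(TRUE, nw)),
    boundary = "walled_x")
  attr(st, "lamellar_span") <- c(0, L[1])
  st
}

#' Relax a stitched box with restrained head beads
#'
#' Runs the dynamics with every C bead tethered to its current position by a
#' harmonic spring, letting the density seam between the lamellar slab and
#' the water column even out without destroying the layer structure.  Tethers
#' are removed on return.
#'
#' @param stitched output of [stitch_dissolution_box()].
#' @param matrix interaction matrix.
#' @param params [dpd_params()].
#' @param steps relaxation steps (default 10000).
#' @param tether_k tether spring constant (default: the bond constant).
#' @param stride monitoring snapshot stride (0 = none).
#' @param seed integer seed.
#' @return The relaxed `dpd_state` (attribute `lamellar_span` preserved);
#'   attribute `relax_trajectory` holds the monitoring trajectory if
#'   `stride > 0`.
#' @export
relax_restrained <- function(stitched, matrix, params = dpd_params(),
                             steps = 10000, tether_k = params$kappa,
                             stride = 0, seed = 1L) {
  c_idx <- which(stitched$species == "C" & !stitched$frozen)
  tethers <- if (length(c_idx) > 0)
    list(index = c_idx, anchor = stitched$positions[c_idx, , drop = FALSE],
         k = tether_k)
  else NULL
  traj <- run_dpd(stitched, matrix, params, steps = steps, stride = stride,
                  seed = seed, tethers = tethers)
  out <- traj$state
  attr(out, "lamellar_span") <- attr(stitched, "lamellar_span")
  if (stride > 0) attr(out, "relax_trajectory") <- traj
  out
}
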