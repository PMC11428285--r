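# Synthetic-data generators: planted micelle fields, step concentration
# boxes and zonal curves with known parameters.  These make every analysis
# stage testable without running long simulations; ground truth is returned
# alongside the configuration so tests never rely on the code under test.

#' Generate a planted micelle configuration with known ground truth
#'
#' Places `n_clusters` compact micelles (random-coil chains confined within
#' `radius` of the cluster centre) at centre-to-centre gaps exceeding
#' 2 * (radius + gap), so the true clustering is unambiguous for any linkage
#' cutoff up to `gap`.  Optional free chains are scattered at least the same
#' margin away from every cluster.
#'
#' @param n_clusters number of planted micelles.
#' @param chains_per_cluster named integer vector: chains of each template
#'   per cluster, e.g. `c("3A2BC" = 10, "4ABC" = 10)`.
#' @param box numeric length-3 box.
#' @param radius cluster radius (default 1.5).
#' @param gap guaranteed clearance between cluster surfaces (default 1.5;
#'   must exceed the linkage cutoff used by the finder).
#' @param oil_per_cluster oil molecules (template `oil_template`) placed
#'   inside each cluster (default 0).
#' @param oil_template template name for the oil (default `"oil2"`).
#' @param n_free_chains isolated chains planted far from all clusters.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap for centre placement.
#' @return List: `state` (a periodic `dpd_state`) and `truth` (list of
#'   chain-id vectors per planted micelle, plus `free_chains`).
#' @export
gen_planted_micelles <- function(n_clusters, chains_per_cluster, box,
                                 radius = 1.5, gap = 1.5,
                                 oil_per_cluster = 0, oil_template = "oil2",
                                 n_free_chains = 0, seed = 1L,
                                 max_tries = 5000) {
  stopifnot(n_clusters >= 0, all(chains_per_cluster >= 0), length(box) == 3)
  set.seed(as.integer(seed))
  templates <- build_molecule_templates(
    unique(c(names(chains_per_cluster), oil_template, "water")))
  min_gap <- 2 * radius + gap
  if (n_clusters > 0 && min_gap > min(box) / 2)
    stop("infeasible packing: clusters of this radius/gap cannot fit the box")
  n_sites <- n_clusters + n_free_chains
  centers <- matrix(NA_real_, n_sites, 3)
  placed <- 0; tries <- 0
  while (placed < n_sites) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("infeasible packing: could not place ", n_sites,
           " separated sites in the box")
    cand <- runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)
      for (dd in 1:3) d[, dd] <- d[, dd] - box[dd] * round(d[, dd] / box[dd])
      ok <- all(rowSums(d^2) > min_gap^2)
    }
    if (ok) { placed <- placed + 1; centers[placed, ] <- cand }
  }
  pos <- list(); species <- list(); mol_id <- list(); mol_name <- list()
  bonds <- list()
  at <- 0L; mol <- 0L
  truth <- vector("list", n_clusters)
  coil <- function(tmpl, center, r_lim) {
    nb <- length(tmpl$beads)
    p <- matrix(0, nb, 3)
    p[1, ] <- center + runif(3, -r_lim / 2, r_lim / 2)
    if (nb > 1) for (j in 2:nb) {
      repeat {
        d <- rnorm(3); d <- d / sqrt(sum(d^2)) * tmpl$r_eq
        cand <- p[j - 1, ] + d
        if (sum((cand - center)^2) <= r_lim^2) { p[j, ] <- cand; break }
      }
    }
    p
  }
  add_mol <- function(tmpl, p) {
    mol <<- mol + 1L
    nb <- length(tmpl$beads)
    pos[[length(pos) + 1]] <<- p
    species[[length(species) + 1]] <<- tmpl$beads
    mol_id[[length(mol_id) + 1]] <<- rep(mol, nb)
    mol_name[[length(mol_name) + 1]] <<- rep(tmpl$name, nb)
    if (nrow(tmpl$bonds) > 0) bonds[[length(bonds) + 1]] <<- tmpl$bonds + at
    at <<- at + nb
    mol
  }
  for (k in seq_len(n_clusters)) {
    ids <- integer(0)
    for (nm in names(chains_per_cluster)) {
      for (i in seq_len(chains_per_cluster[[nm]]))
        ids <- c(ids, add_mol(templates[[nm]], coil(templates[[nm]],
                                                    centers[k, ], radius)))
    }
    for (i in seq_len(oil_per_cluster))
      add_mol(templates[[oil_template]],
              coil(templates[[oil_template]], centers[k, ], radius * 0.6))
    truth[[k]] <- ids
  }
  free_ids <- integer(0)
  free_tmpl <- templates[[names(chains_per_cluster)[1]]]
  for (i in seq_len(n_free_chains))
    free_ids <- c(free_ids, add_mol(free_tmpl,
                                    coil(free_tmpl, centers[n_clusters + i, ],
                                         radius)))
  if (at == 0L)
    stop("nothing to generate: no clusters and no free chains")
  st <- dpd_state(do.call(rbind, pos), unlist(species), box,
                  molecule_id = unlist(mol_id),
                  molecule_name = unlist(mol_name),
                  bonds = if (length(bonds) > 0) do.call(rbind, bonds) else NULL,
                  boundary = "periodic")
  list(state = st, truth = list(clusters = truth, free_chains = free_ids))
}

#' Generate zonal curves with known parameters
#'
#' Forward-simulates the compartment model and adds i.i.d. Gaussian noise,
#' seeded; drives the parameter-recovery tests of [fit_zonal_parameters()].
#'
#' @inheritParams simulate_zonal_ode
#' @param noise_sd standard deviation of the additive noise (0 = exact).
#' @param n_points number of time points.
#' @param t_max final time (default 100).
#' @param seed integer seed.
#' @return A `zonal_series`.
#' @export
gen_zonal_curves <- function(k_trans, D, noise_sd = 0, n_points = 200,
                             t_max = 100,
                             initial = c(0.8, rep(0, 5)),
                             vol_S = 1, vol_zone = 1, seed = 1L) {
  stopifnot(noise_sd >= 0, n_points >= 2)
  times <- seq(0, t_max, length.out = n_points)
  ser <- simulate_zonal_ode(k_trans, D, initial, times, vol_S, vol_zone)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    zc <- c("C_S", zone_columns(ser))
    for (cc in zc)
      ser[[cc]] <- pmax(0, ser[[cc]] + rnorm(nrow(ser), sd = noise_sd))
  }
  ser
}

#' Generate a step concentration box
#'
#' Fills a box at density rho with single-bead surfactant (species A) mixed
#' at concentration `conc_left` in the left `fraction_left` of the x-range
#' and pure water elsewhere.  Used for closed-form checks of the profile and
#' homogeneity metrics.
#'
#' @param fraction_left fraction of the box length occupied by the
#'   surfactant-bearing region (in `[0, 1]`).
#' @param box numeric length-3 box.
#' @param conc_left surfactant bead fraction inside the left region
#'   (default 1).
#' @param rho bead density (default 3).
#' @param seed integer seed.
#' @return A periodic `dpd_state`.
#' @export
gen_step_concentration_box <- function(fraction_left, box, conc_left = 1,
                                       rho = 3, seed = 1L) {
  stopifnot(fraction_left >= 0, fraction_left <= 1,
            conc_left >= 0, conc_left <= 1)
  set.seed(as.integer(seed))
  N <- round(rho * prod(box))
  x <- runif(N) * box[1]
  y <- runif(N) * box[2]
  z <- runif(N) * box[3]
  left <- x < fraction_left * box[1]
  species <- rep("W", N)
  n_left <- sum(left)
  if (n_left > 0)
    species[left][runif(n_left) < conc_left] <- "A"
  dpd_state(cbind(x, y, z), species, box, boundary = "periodic")
}
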