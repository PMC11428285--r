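# Shared fixtures: the resolved interaction matrix (the shipped raw table is
# asymmetric in A-O by construction, so building it always warns) and small
# reference systems built in code.

ff_matrix <- suppressWarnings(build_interaction_matrix())

# a pure single-species fluid at density 3
make_fluid <- function(L = 7, species = "W", seed = 1L) {
  st <- build_random_box(
    composition_spec(c(water = 1), c(L, L, L)),
    build_molecule_templates("water"), seed = seed)
  st$species[] <- species
  st
}

# two beads at a given separation along x, in a roomy periodic box
make_pair <- function(r, species = c("A", "A"), box = c(6, 6, 6),
                      bonds = NULL, velocities = NULL) {
  dpd_state(rbind(c(2, 3, 3), c(2 + r, 3, 3)), species, box,
            bonds = bonds, velocities = velocities)
}

# ideal lamellar stack: n_layers slabs of A beads alternating with W along
# `axis`; a planted configuration with a perfect density wave
make_perfect_lamellae <- function(L = 10, n_layers = 4, axis = 1,
                                  rho = 3, seed = 1L) {
  set.seed(seed)
  N <- round(rho * L^3)
  u <- runif(N) * L
  period <- L / n_layers
  in_slab <- (u %% period) < period / 2
  other <- matrix(runif(2 * N) * L, N, 2)
  pos <- matrix(0, N, 3)
  pos[, axis] <- u
  pos[, setdiff(1:3, axis)] <- other
  dpd_state(pos, ifelse(in_slab, "A", "W"), c(L, L, L))
}

# brute-force O(n^2) single-linkage chain clustering, the independent oracle
# for find_micelles
brute_force_clusters <- function(state, cutoff = 1.0, min_chains = 4L) {
  per <- c(state$boundary != "walled_x", TRUE, TRUE)
  surf <- !state$frozen & state$species == "A" &
    state$molecule_id %in% state$molecule_id[unique(as.vector(state$bonds))]
  chain_ids <- unique(state$molecule_id[surf])
  nch <- length(chain_ids)
  if (nch == 0) return(list())
  pos <- state$positions[surf, , drop = FALSE]
  chain <- match(state$molecule_id[surf], chain_ids)
  adj <- matrix(FALSE, nch, nch)
  nb <- nrow(pos)
  for (i in seq_len(nb - 1)) {
    d <- sweep(pos[(i + 1):nb, , drop = FALSE], 2, pos[i, ])
    for (dd in 1:3) if (per[dd]) {
      L <- state$box[dd]
      d[, dd] <- d[, dd] - L * round(d[, dd] / L)
    }
    hit <- which(rowSums(d^2) <= cutoff^2) + i
    for (j in hit) {
      adj[chain[i], chain[j]] <- TRUE
      adj[chain[j], chain[i]] <- TRUE
    }
  }
  lab <- seq_len(nch)
  repeat {
    changed <- FALSE
    for (i in seq_len(nch)) {
      nbrs <- which(adj[i, ])
      if (length(nbrs) > 0) {
        m <- min(lab[c(i, nbrs)])
        if (any(lab[c(i, nbrs)] != m)) {
          lab[c(i, nbrs)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  groups <- split(chain_ids, lab)
  groups <- groups[vapply(groups, length, 1L) >= min_chains]
  unname(lapply(groups, sort))
}

# canonical form of a clustering: sorted list of sorted chain-id vectors
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, min, 1))]
}
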