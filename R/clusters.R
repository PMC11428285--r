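# Micelle identification by single-linkage chain clustering on hydrophobic
# beads, aggregation-number statistics and the 1/V^(1/3) size metric.

#' Identify micelles in a snapshot
#'
#' Surfactant chains (bonded molecules containing A beads) are linked
#' whenever any pair of their hydrophobic A beads lies within `cutoff`
#' (minimum image in the periodic directions); micelles are the connected
#' components of this chain graph.  Groups of three or fewer chains are
#' counted as free surfactant and dropped.  Each oil molecule is attached to
#' the micelle of the nearest clustered A bead within `cutoff`, else left
#' unassigned.
#'
#' @param state a `dpd_state`.
#' @param cutoff linkage distance in r_c (default 1.0).
#' @param min_chains smallest chain count that still counts as a micelle
#'   (default 4, i.e. clusters of <= 3 chains are excluded).
#' @return A `micelle_set`: list with `clusters` (list of chain-id vectors),
#'   `n_chains`, `surf_beads`, `oil_beads`, `composition` (per-cluster named
#'   chain counts per template), `free_chains` (chain ids in dropped groups),
#'   `total_chains`, `oil_assignment` (cluster per oil molecule, NA if free).
#' @export
find_micelles <- function(state, cutoff = 1.0, min_chains = 4L) {
  stopifnot(cutoff > 0)
  per <- c(state$boundary != "walled_x", TRUE, TRUE)
  is_surf_bead <- !state$frozen & state$molecule_name %in% c("3A2BC", "4ABC")
  # fall back on topology for unusual templates: bonded molecules with A beads
  if (!any(is_surf_bead)) {
    bonded <- state$molecule_id %in% state$molecule_id[unique(as.vector(state$bonds))]
    has_a <- state$molecule_id %in% unique(state$molecule_id[state$species == "A"])
    is_surf_bead <- !state$frozen & bonded & has_a
  }
  chain_ids <- unique(state$molecule_id[is_surf_bead])
  nchain <- length(chain_ids)
  empty <- structure(list(clusters = list(), n_chains = integer(0),
                          surf_beads = integer(0), oil_beads = integer(0),
                          composition = list(), free_chains = chain_ids,
                          total_chains = nchain,
                          oil_assignment = integer(0)),
                     class = "micelle_set")
  if (nchain == 0) return(empty)
  a_sel <- which(is_surf_bead & state$species == "A")
  chain_of <- match(state$molecule_id[a_sel], chain_ids)
  lab <- cpp_link_chains(state$positions[a_sel, , drop = FALSE],
                         as.integer(chain_of), nchain, state$box,
                         per, cutoff)
  groups <- split(chain_ids, lab)
  keep <- vapply(groups, length, 1L) >= min_chains
  clusters <- unname(groups[keep])
  free_chains <- unlist(groups[!keep], use.names = FALSE)
  if (length(clusters) == 0) {
    empty$free_chains <- chain_ids
    return(empty)
  }
  # per-cluster bead counts and composition
  mol_name_of_chain <- state$molecule_name[match(chain_ids, state$molecule_id)]
  beads_per_mol <- tabulate(state$molecule_id, nbins = max(state$molecule_id))
  n_chains <- vapply(clusters, length, 1L)
  surf_beads <- vapply(clusters, function(ch) sum(beads_per_mol[ch]), 1L)
  composition <- lapply(clusters, function(ch) {
    table(mol_name_of_chain[match(ch, chain_ids)])
  })
  # oil assignment: nearest clustered A bead within cutoff
  oil_mols <- unique(state$molecule_id[state$species == "O" & !state$frozen])
  oil_assignment <- integer(0)
  oil_beads <- rep(0L, length(clusters))
  if (length(oil_mols) > 0) {
    cl_of_chain <- integer(nchain)
    for (k in seq_along(clusters))
      cl_of_chain[match(clusters[[k]], chain_ids)] <- k
    a_pos <- state$positions[a_sel, , drop = FALSE]
    a_cl <- cl_of_chain[chain_of]
    clustered <- a_cl > 0
    oil_assignment <- vapply(oil_mols, function(m) {
      op <- state$positions[state$molecule_id == m, , drop = FALSE]
      best_d <- Inf; best_cl <- NA_integer_
      ap <- a_pos[clustered, , drop = FALSE]
      acl <- a_cl[clustered]
      if (nrow(ap) == 0) return(NA_integer_)
      for (r in seq_len(nrow(op))) {
        d <- sweep(ap, 2, op[r, ])
        for (dd in 1:3) {
          if (per[dd]) {
            L <- state$box[dd]
            d[, dd] <- d[, dd] - L * round(d[, dd] / L)
          }
        }
        d2 <- rowSums(d^2)
        j <- which.min(d2)
        if (d2[j] < best_d) { best_d <- d2[j]; best_cl <- acl[j] }
      }
      if (best_d <= cutoff^2) best_cl else NA_integer_
    }, 1L)
    tab <- table(factor(oil_assignment, levels = seq_along(clusters)))
    oil_counts <- as.integer(tab)
    oil_sizes <- vapply(oil_mols, function(m) sum(state$molecule_id == m), 1L)
    for (k in seq_along(clusters))
      oil_beads[k] <- sum(oil_sizes[which(oil_assignment == k)])
  }
  structure(list(clusters = clusters, n_chains = n_chains,
                 surf_beads = as.integer(surf_beads),
                 oil_beads = as.integer(oil_beads),
                 composition = composition, free_chains = free_chains,
                 total_chains = nchain,
                 oil_assignment = oil_assignment),
            class = "micelle_set")
}

#' @export
print.micelle_set <- function(x, ...) {
  cat(sprintf("<micelle_set> %d micelle(s), %d free chain(s) of %d total\n",
              length(x$clusters), length(x$free_chains), x$total_chains))
  if (length(x$n_chains) > 0)
    cat(sprintf("  chains per micelle: mean %.1f, range %d-%d\n",
                mean(x$n_chains), min(x$n_chains), max(x$n_chains)))
  invisible(x)
}

#' Micelle summary statistics and the 1/V^(1/3) size metric
#'
#' Mean aggregation number, micelle count, mean micelle volume V (total bead
#' count per cluster: surfactant beads plus any oil beads assigned to the
#' cluster, with unit bead volume) and the size metric V^(-1/3).  Under
#' Stokes-Einstein behaviour of a solid sphere the metric is proportional to
#' the micelle diffusion constant.
#'
#' @param mset a [find_micelles()] result.
#' @return List `mean_chains`, `n_micelles`, `mean_volume`, `size_metric`,
#'   `empty` flag (all-zero summary when no micelles were found).
#' @export
micelle_statistics <- function(mset) {
  stopifnot(inherits(mset, "micelle_set"))
  if (length(mset$clusters) == 0)
    return(list(mean_chains = 0, n_micelles = 0L, mean_volume = 0,
                size_metric = 0, empty = TRUE))
  V <- mean(mset$surf_beads + mset$oil_beads)
  list(mean_chains = mean(mset$n_chains),
       n_micelles = length(mset$clusters),
       mean_volume = V,
       size_metric = V^(-1 / 3),
       empty = FALSE)
}

#' Size metric from a mean aggregation number
#'
#' The arithmetic identity behind the summary tables: for chains of
#' `beads_per_chain` beads, the mean micelle volume is
#' V = mean_chains * beads_per_chain * (1 + oil_bead_ratio), where
#' `oil_bead_ratio` is the oil:surfactant bead ratio inside the micelles
#' (10:70 for the oil-loaded systems, 0 for oil-free ones), and the metric is
#' V^(-1/3).
#'
#' @param mean_chains mean chains per micelle.
#' @param beads_per_chain beads in one surfactant chain (default 6).
#' @param oil_bead_ratio oil beads per surfactant bead inside micelles.
#' @return Scalar V^(-1/3).
#' @export
aggregate_size_metric <- function(mean_chains, beads_per_chain = 6,
                                  oil_bead_ratio = 0) {
  stopifnot(mean_chains > 0, beads_per_chain > 0, oil_bead_ratio >= 0)
  V <- mean_chains * beads_per_chain * (1 + oil_bead_ratio)
  V^(-1 / 3)
}

#' Per-micelle surfactant composition and mixing index
#'
#' For mixed-surfactant systems: the fraction of each surfactant type in
#' every micelle and the population mixing index, the (population) standard
#' deviation of the per-micelle fraction of the first type.  Zero means all
#' micelles share the global composition; demixed micelles maximize it.
#'
#' @param mset a [find_micelles()] result.
#' @return data.frame with one row per micelle (`cluster`, one column per
#'   template name, `n_chains`), attribute `mixing_index`.
#' @export
micelle_composition <- function(mset) {
  stopifnot(inherits(mset, "micelle_set"))
  if (length(mset$clusters) == 0)
    return(structure(data.frame(), mixing_index = NA_real_))
  types <- sort(unique(unlist(lapply(mset$composition, names))))
  fr <- vapply(mset$composition, function(tb) {
    v <- as.numeric(tb[types])
    v[is.na(v)] <- 0
    v / sum(v)
  }, numeric(length(types)))
  fr <- t(matrix(fr, nrow = length(types)))
  colnames(fr) <- types
  out <- data.frame(cluster = seq_along(mset$clusters), fr,
                    n_chains = mset$n_chains, check.names = FALSE)
  f1 <- fr[, 1]
  attr(out, "mixing_index") <- sqrt(mean((f1 - mean(f1))^2))
  out
}
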