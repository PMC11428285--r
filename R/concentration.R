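# Local concentration profiles along x and the homogeneity (standard
# deviation of concentration) metric used to track dissolution.

#' Concentration profile along x
#'
#' Bins the box along x (default bin width 0.332 r_c; the final partial bin
#' is merged with its neighbour) and reports, per bin, the fraction of free
#' beads that belong to `species_set`, with y and z averaged out.  Frozen
#' wall beads are excluded from numerator and denominator.  Concentration is
#' bead-count fraction, i.e. volume fraction at unit bead volume.
#'
#' @param state a `dpd_state`.
#' @param species_set character vector of species labels to count (e.g.
#'   `c("A","B","C")` for one surfactant's beads, or `"O"` for oil).
#' @param bin_width bin width along x in r_c (default 0.332).
#' @return A `concentration_profile`: data.frame with `bin_center`, `value`,
#'   `n_beads`; attributes `bin_width`, `empty_bins` (flagged indices).
#' @export
concentration_profile <- function(state, species_set, bin_width = 0.332) {
  stopifnot(bin_width > 0)
  Lx <- state$box[1]
  nb <- max(1L, floor(Lx / bin_width))
  edges <- seq(0, by = bin_width, length.out = nb + 1)
  edges[nb + 1] <- Lx   # merge trailing partial bin into the last bin
  free <- !state$frozen
  x <- state$positions[free, 1]
  inset <- state$species[free] %in% species_set
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tot <- tabulate(bin, nbins = nb)
  hit <- tabulate(bin[inset], nbins = nb)
  val <- ifelse(tot > 0, hit / tot, 0)
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  out <- data.frame(bin_center = centers, value = val, n_beads = tot)
  class(out) <- c("concentration_profile", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "empty_bins") <- which(tot == 0)
  out
}

#' Homogeneity metric: standard deviation of a concentration profile
#'
#' Population standard deviation of the per-bin concentrations (unweighted
#' over bins).  Zero for a perfectly homogeneous box; large when the species
#' is piled up at one end.
#'
#' @param profile a [concentration_profile()].
#' @return Scalar standard deviation.
#' @export
homogeneity_std <- function(profile) {
  v <- profile$value
  if (length(v) < 2) stop("need at least 2 bins")
  sqrt(mean((v - mean(v))^2))
}

#' Homogeneity time series over a trajectory
#'
#' Computes [homogeneity_std()] for every snapshot, plus a trend summary:
#' the end of the initial plateau (last time the value stays above 95% of
#' its initial level) and the slope of the falling branch (linear fit beyond
#' the plateau).
#'
#' @param traj a `dpd_trajectory` with at least 2 snapshots.
#' @param species_set species labels to track.
#' @param bin_width profile bin width.
#' @return data.frame (`time`, `std`) with attribute `trend` = list
#'   (`plateau_end`, `slope`).
#' @export
homogeneity_series <- function(traj, species_set, bin_width = 0.332) {
  ns <- n_snapshots(traj)
  if (ns < 2) stop("need at least 2 snapshots")
  std <- vapply(seq_len(ns), function(i)
    homogeneity_std(concentration_profile(get_snapshot(traj, i), species_set,
                                          bin_width)), 1.0)
  out <- data.frame(time = traj$times, std = std)
  above <- which(std >= 0.95 * std[1])
  plateau_end <- if (length(above) > 0) traj$times[max(above)] else traj$times[1]
  falling <- out[out$time >= plateau_end, ]
  slope <- if (nrow(falling) >= 2)
    unname(coef(lm(std ~ time, data = falling))[2]) else NA_real_
  attr(out, "trend") <- list(plateau_end = plateau_end, slope = slope)
  out
}
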