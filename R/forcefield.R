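#' Bead species of the coarse-grained surfactant model
#'
#' The model distinguishes five bead types: `A` (hydrophobic tail fragment,
#' -C3H6-), `B` (hydrophilic -EO2-), `C` (hydrophilic sulfate head -OSO3-),
#' `W` (water, four molecules per bead) and `O` (oil, chemically identical to
#' the tail fragment).  All beads carry reduced mass 1; the physical mass is
#' metadata used only for unit conversion.
#'
#' @return A data.frame with columns `label`, `mass` (reduced, all 1) and
#'   `fragment` (a human-readable description).
#' @export
bead_species <- function() {
  data.frame(
    label = c("A", "B", "C", "W", "O"),
    mass = 1,
    fragment = c("-C3H6- tail", "-EO2- head", "-OSO3- head",
                 "4 x H2O", "-C3H6- oil"),
    stringsAsFactors = FALSE
  )
}

#' Default bead-bead repulsion table
#'
#' The maximum-repulsion parameters A_ij (reduced units) between the five bead
#' species, as used throughout the package.  The raw table is returned exactly
#' as parametrized, including its one asymmetric entry (A-O: the A row carries
#' 106.5, the O row 126.5); [build_interaction_matrix()] resolves the conflict.
#'
#' @return A 5 x 5 numeric matrix with dimnames `A,B,C,W,O`.
#' @export
default_interaction_table <- function() {
  lab <- c("A", "B", "C", "W", "O")
  m <- matrix(c(
    106.5, 113.0, 127.7, 126.5, 106.5,
    113.0, 106.5, 106.5, 107.5, 113.0,
    127.7, 106.5, 106.5,  83.0, 127.7,
    126.5, 107.5,  83.0, 106.5, 126.5,
    126.5, 113.0, 127.7, 126.5, 106.5), nrow = 5, byrow = TRUE,
    dimnames = list(lab, lab))
  m
}

#' Build a validated, symmetric interaction matrix
#'
#' Validates a raw repulsion table and returns a symmetric
#' `interaction_matrix`.  If the raw input is asymmetric in some pair the
#' conflict is resolved by `resolve` and a warning is emitted.  The default
#' rule `"upper"` keeps the upper-triangle entry (row earlier in the species
#' order); for the shipped table this retains A-O = 106.5, consistent with
#' oil beads being chemically identical to the A tail fragment (A-A = 106.5).
#'
#' @param raw_table square numeric matrix with species dimnames, or `NULL`
#'   for [default_interaction_table()].
#' @param resolve one of `"upper"`, `"lower"`, `"min"`, `"max"`: which of two
#'   conflicting symmetric entries to keep.
#' @return A symmetric matrix of class `interaction_matrix`.
#' @export
build_interaction_matrix <- function(raw_table = NULL,
                                     resolve = c("upper", "lower", "min", "max")) {
  resolve <- match.arg(resolve)
  if (is.null(raw_table)) raw_table <- default_interaction_table()
  if (!is.matrix(raw_table) || nrow(raw_table) != ncol(raw_table))
    stop("interaction table must be a square matrix")
  lab <- rownames(raw_table)
  if (is.null(lab) || !identical(lab, colnames(raw_table)))
    stop("interaction table needs matching row/column species names")
  if (anyDuplicated(lab)) stop("species labels must be unique")
  required <- bead_species()$label
  missing <- setdiff(required, lab)
  if (length(missing) > 0)
    stop("missing species in interaction table: ", paste(missing, collapse = ", "))
  if (any(!is.finite(raw_table)))
    stop("configuration error: interaction table has missing entries")
  if (any(raw_table <= 0))
    stop("validation error: all repulsion parameters must be > 0")
  m <- raw_table
  asym <- which(abs(m - t(m)) > 1e-12 & upper.tri(m), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    pairs <- apply(asym, 1, function(ij) paste0(lab[ij[1]], "-", lab[ij[2]]))
    warning("asymmetric interaction table in pair(s) ",
            paste(pairs, collapse = ", "), "; resolved by rule '", resolve, "'")
    for (k in seq_len(nrow(asym))) {
      i <- asym[k, 1]; j <- asym[k, 2]
      v <- switch(resolve,
                  upper = m[i, j], lower = m[j, i],
                  min = min(m[i, j], m[j, i]), max = max(m[i, j], m[j, i]))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m <- (m + t(m)) / 2  # exact symmetry against round-off
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' Molecule templates (bead sequence and bond topology)
#'
#' A template is a simple bead-spring path: the bead sequence plus bonds
#' between consecutive beads, all sharing one spring constant and equilibrium
#' length.  Known molecules:
#' * `3A2BC`: A,A,A,B,B,C (5 bonds) -- base anionic surfactant;
#' * `4ABC`: A,A,A,A,B,C (5 bonds) -- longer-tailed, smaller-headed surfactant;
#' * `oil1`..`oil4`: chains of 1-4 `O` beads;
#' * `water`: a single unbonded `W` bead.
#'
#' @param names character vector of molecule names to build.
#' @param kappa bond spring constant (reduced units).
#' @param r_eq equilibrium bond length (reduced units).
#' @return A named list of `molecule_template` objects, each with fields
#'   `name`, `beads` (species labels), `bonds` (m x 2 integer matrix),
#'   `kappa`, `r_eq`.
#' @export
build_molecule_templates <- function(names = c("3A2BC", "4ABC", "water"),
                                     kappa = 75, r_eq = 0.45) {
  make <- function(name, beads) {
    nb <- length(beads)
    bonds <- if (nb > 1) cbind(seq_len(nb - 1), seq_len(nb - 1) + 1L)
             else matrix(integer(0), ncol = 2)
    structure(list(name = name, beads = beads, bonds = bonds,
                   kappa = kappa, r_eq = r_eq),
              class = "molecule_template")
  }
  out <- lapply(names, function(nm) {
    if (nm == "3A2BC") return(make(nm, c("A", "A", "A", "B", "B", "C")))
    if (nm == "4ABC") return(make(nm, c("A", "A", "A", "A", "B", "C")))
    if (nm == "water") return(make(nm, "W"))
    if (grepl("^oil[1-9][0-9]*$", nm)) {
      n <- as.integer(sub("^oil", "", nm))
      if (n >= 1 && n <= 4) return(make(nm, rep("O", n)))
    }
    stop("configuration error: unknown molecule name '", nm, "'")
  })
  names(out) <- names
  out
}

#' @export
print.molecule_template <- function(x, ...) {
  cat("<molecule_template>", x$name, ":", paste(x$beads, collapse = ""),
      sprintf("(%d beads, %d bonds, kappa=%g, r_eq=%g)\n",
              length(x$beads), nrow(x$bonds), x$kappa, x$r_eq))
  invisible(x)
}

#' Simulation parameters
#'
#' Collects the reduced-unit DPD parameters.  The noise amplitude is always
#' derived from the friction via the fluctuation-dissipation relation
#' sigma^2 = 2 gamma k_B T, which makes the dissipative/random pair act as a
#' momentum-conserving thermostat at temperature `kT`.
#'
#' @param dt integration time step (default 0.02).
#' @param r_c interaction cutoff; fixed at 1 (the reduced unit of length).
#' @param kT thermostat temperature in reduced energy units (default 1).
#' @param rho target bead number density (default 3).
#' @param gamma friction coefficient (default 4.5).
#' @param kappa bond spring constant (default 75).
#' @param r_eq equilibrium bond length (default 0.45).
#' @param A_wall wall repulsion magnitude (default 106.5, the self-repulsion).
#' @param z_c wall repulsion range (default 1).
#' @param seed integer RNG seed for the engine.
#' @return A list of class `dpd_params` including the derived `sigma`.
#' @export
dpd_params <- function(dt = 0.02, r_c = 1, kT = 1, rho = 3, gamma = 4.5,
                       kappa = 75, r_eq = 0.45, A_wall = 106.5, z_c = 1,
                       seed = 1L) {
  stopifnot(dt > 0, r_c == 1, kT > 0, rho > 0, gamma >= 0,
            kappa >= 0, r_eq >= 0, A_wall >= 0, z_c > 0)
  structure(list(dt = dt, r_c = r_c, kT = kT, rho = rho, gamma = gamma,
                 sigma = sqrt(2 * gamma * kT), kappa = kappa, r_eq = r_eq,
                 A_wall = A_wall, z_c = z_c, seed = as.integer(seed)),
            class = "dpd_params")
}

#' Physical unit mapping of the coarse-grained model
#'
#' One W bead lumps four water molecules, which fixes the physical bead mass;
#' matching the simulated bead density rho to the real number density of
#' liquid water fixes the physical length of the cutoff r_c.  Both are
#' metadata: the simulation itself runs in reduced units.
#'
#' @param rho reduced bead density the mapping assumes (default 3).
#' @param n_water_per_bead water molecules lumped into one bead (default 4).
#' @param water_density_kg_m3 mass density of water at the simulated
#'   temperature, 298 K (default 997 kg/m^3).
#' @return List with `bead_mass_kg` and `r_c_m`.
#' @export
physical_units <- function(rho = 3, n_water_per_bead = 4,
                           water_density_kg_m3 = 997) {
  avogadro <- 6.02214076e23
  m_water <- 18.01528e-3 / avogadro          # kg per molecule
  bead_mass <- n_water_per_bead * m_water
  n_density_water <- water_density_kg_m3 / m_water   # molecules / m^3
  # rho beads per r_c^3, each bead n_water_per_bead molecules
  r_c <- (rho * n_water_per_bead / n_density_water)^(1 / 3)
  list(bead_mass_kg = bead_mass, r_c_m = r_c)
}
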