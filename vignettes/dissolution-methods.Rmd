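---
title: "Modelling surfactant lamellar-phase dissolution with dpdiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling surfactant lamellar-phase dissolution with dpdiss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdiss)
```

## The model

`dpdiss` simulates the dissolution of concentrated surfactant lamellar
phases with dissipative particle dynamics (DPD).  Beads interact through
three pairwise forces inside a cutoff $r_c = 1$:

* a soft conservative repulsion $F^C_{ij} = A_{ij}\,(1 - r_{ij}/r_c)\,\hat r_{ij}$,
* a dissipative drag $F^D_{ij} = -\gamma\, w_D(r)\,(\hat r_{ij} \cdot v_{ij})\,\hat r_{ij}$,
* a random kick $F^R_{ij} = \sigma\, w_R(r)\, \zeta_{ij}\, \Delta t^{-1/2}\, \hat r_{ij}$,

with $w_D = w_R^2 = (1 - r/r_c)^2$ and one Gaussian variate $\zeta_{ij}$
shared per pair and step.  The fluctuation–dissipation constraint
$\sigma^2 = 2\gamma k_BT$ makes the last two forces a momentum-conserving
thermostat; it is derived inside `dpd_params()` and can never be set
inconsistently.  Bonded beads add a harmonic term
$F = -\kappa (r - r_\mathrm{eq})\hat r$.  Integration uses the
Groot–Warren modified velocity-Verlet scheme with $\lambda = 1/2$; pair
search uses a cell list rebuilt every step (cells $\ge r_c$), with an
all-pairs fallback when a periodic direction is narrower than three cells.

The amphiphile is a six-bead chain: `3A2BC` = AAABBC, with a three-bead
hydrophobic tail (A, $-\mathrm{C_3H_6}-$), two ethoxy head beads (B) and a
sulfate head bead (C); `4ABC` = AAAABC trades a head bead for tail length.
Water beads (W) lump four molecules; oil beads (O) are chemically identical
to A and come in chains of one to four.  No explicit charge is carried: the
stronger hydration of the ionic head is encoded in the low C–W repulsion
(83 vs. the 106.5 self-repulsion).

### Parameters and units

All quantities are reduced ($r_c = k_BT = m = 1$).  Defaults, all exposed
in `dpd_params()`:

| parameter | default | meaning |
|---|---|---|
| $\Delta t$ | 0.02 | integration step |
| $\rho$ | 3 | bead number density |
| $\gamma$ | 4.5 | thermostat friction |
| $\kappa$ | 75 | bond spring constant |
| $r_\mathrm{eq}$ | 0.45 | equilibrium bond length |
| $A_\mathrm{wall}$ | 106.5 | wall repulsion magnitude |
| $z_c$ | 1 | wall repulsion range |

The physical mapping (metadata only) follows from the coarse-graining:
four waters per bead give $1.2\times10^{-25}$ kg, and matching $\rho = 3$
to the number density of liquid water at 298 K gives
$r_c = 7.1\times10^{-10}$ m (`physical_units()`).

The shipped repulsion table is asymmetric in its A–O entry (the A row says
106.5, the O row 126.5).  Since O beads are chemically identical to A beads
and A–A = 106.5, `build_interaction_matrix()` resolves the conflict to
106.5, warns, and leaves the rule configurable (`resolve = "max"`
reproduces the other reading).

### Walls

Dissolution boxes are periodic in $y,z$ and bounded in $x$ by a quadratic
repulsive potential $A_\mathrm{wall}(1 - z/z_c)^2$ ($z$ = distance to the
boundary plane; force magnitude $2A_\mathrm{wall}(1-z/z_c)/z_c$, clamped
for beads that penetrate beyond the plane) plus two rows of frozen W beads
per end.  Frozen beads interact but are not integrated.

## The two-stage experiment

`run_pipeline()` executes the full protocol: build a mixed box at 80 vol%
surfactant, equilibrate, rotate/crop the lamellar stack to `n_layers`
periods along $x$, stitch a pre-equilibrated water column behind walls,
relax for 10$^4$ steps with every C bead tethered to its position
(spring constant 75, the bond value, configurable), then run the
dissolution and the analysis stack.  The combined box length is derived
from the 20 vol% end-concentration target rather than hard-coded; at 80%
initial concentration it is four times the slab length, which reproduces
the published 79/91/99 $r_c$ box lengths for slabs of 19.75/22.75/24.75
$r_c$.

### Equilibration at desk scale, and what it can show

Two observables monitor mesophase formation:

* `structure_factor()` — axis-aligned density waves of the tail beads.
  At 80% surfactant the *total* amphiphile density is nearly uniform, so
  layering is detected on the A beads, whose density alternates between
  bilayer cores and head/water galleries.
* `structure_factor_radial()` / `detect_density_wave()` — the same
  intensity binned over shells of $|k|$, orientation-free.

At the problem sizes the test suite uses (boxes of 10 $r_c$, ~3,000
beads, schedules of a few thousand steps) a random 80 vol% `3A2BC` box
develops a clear microphase-separation wave with spacing $\approx 5\,r_c$
— the acceptance checks compute exactly this — while the *orientational*
annealing of that wave onto a single flat stack does not complete: the
intensity stays spread over the $|k|$-shell instead of condensing onto
one axis.  This is the familiar defect-annealing bottleneck of strongly
segregated lamellar formers, not an instability of the phase.  The package
therefore (a) verifies the *density wave* from random starts, and (b) seeds
the *aligned* stack for the dissolution protocol
(`build_random_box(arrange = "layered")`), relaxing it under full dynamics
before cropping — an unstable seeded stack would melt, so the arrangement
biases the starting point, not the verdict.  Full-scale spontaneous
alignment is a cluster-scale computation and is outside what the tests can
demonstrate about real systems.

Lamellar-normal detection for cropping is restricted to axis permutations:
in small periodic boxes a stack that is aligned at all is axis-aligned,
and the crop geometry only makes sense for axis normals.

## Analysis stack

**Concentration profiles.**  Bead-count fractions in $x$-bins of width
0.332 $r_c$ (the final partial bin merges with its neighbour); wall beads
are excluded on both sides of the division.  The homogeneity metric is the
*unweighted population* standard deviation over bins — bins, not beads,
are the sampling unit, matching the interpretation of the concentration
field as a function of $x$.  `homogeneity_series()` adds a trend summary
(end of the initial plateau, slope of the falling branch).

**Micelle clustering.**  Two surfactant chains are linked when any pair of
their A beads lies within $r_\mathrm{cl}$ (default 1.0 $r_c$; single
linkage, union-find, cell-list accelerated with an $O(n^2)$ fallback and
an independent brute-force oracle in the tests).  Clusters of three or
fewer chains are free surfactant, not micelles.  Oil molecules attach to
the cluster of the nearest clustered A bead within the cutoff.  Micelle
volume is the total bead count (unit bead volume) including assigned oil,
and the size metric is $V^{-1/3}$ — with the exponent computed as exactly
$1/3$: the published tables print "$1/V^{0.33}$", but only the cube root
reproduces their values at three decimals.  The linkage criterion and
cutoff are configurable because the upstream clustering algorithm is cited
rather than specified; the size-metric identity is cutoff-independent.

**Zonal model.**  The dissolution kinetics are compressed into a
compartment model: the lamellar zone (its $x$-span frozen at $t=0$)
transforms at first order, $\dot C_S = -k_\mathrm{trans} C_S$, feeding
zone 1 of five equal slabs with the volume ratio $V_S/V_1$ (which makes
the mass balance exact), while neighbouring zones exchange Fickian flux
$\dot C_i = D\,(C_{i-1} - 2C_i + C_{i+1})$ with closed outer boundaries.
$D$ absorbs the (zone width)$^{-2}$ geometric factor and is reported in
model units; no physical conversion is attempted.  The system is linear,
so the forward model is solved by eigendecomposition (lsoda fallback for
near-defective spectra).  `fit_zonal_parameters()` does joint
Levenberg–Marquardt least squares over all six curves on log-parameters
(positivity by construction) from a multi-start grid scaled by the data's
time span, and flags degenerate inputs instead of fitting them: a constant
$C_S$ pins $k_\mathrm{trans}$ at 0, flat zone curves leave $D$
unidentifiable.  Whether the original analysis fitted the two stages
jointly or sequentially is ambiguous; we fit jointly and report the
residual.

**Identifiability caveat.**  When $D$ is much faster than the sampling
interval the zones stay mutually equilibrated and $D$ is effectively
unbounded from above; recovery tests with noise therefore use parameters
in the identifiable regime, while the noiseless self-consistency check
uses a deliberately stiff pair.

## Synthetic data

Fixtures are generated, never stored: planted micelles (coiled chains
confined within a radius, centres separated by more than twice the
linkage cutoff so ground truth is unambiguous), step concentration boxes
(closed-form profile and standard-deviation oracles), and zonal curves
with known $(k_\mathrm{trans}, D)$ plus seeded Gaussian noise.  Ground
truth is returned by the generator and consumed directly by the tests.
These fixtures emulate the *geometry* of micellar configurations and the
*algebra* of the kinetic model; they do not emulate thermal disorder,
polydispersity or micelle-micelle interactions, so tests passing on them
demonstrate the correctness of the analysis code, not the realism of the
dynamics.

## Numerical choices

* Integration instability (per-step displacement $> r_c$) and NaNs abort
  with the step number; bonds stretched beyond half the smallest box edge
  are a hard error (minimum-image ambiguity).
* Exactly overlapping beads receive the full conservative magnitude
  $A_{ij}$ along a random direction (the soft potential has no
  singularity).
* Pressure is the conservative-virial estimate
  $p = \rho_\mathrm{free} k_BT + W_C/3V$ averaged over the second half of
  a run.  Against the classic soft-sphere equation-of-state estimate
  $p \approx \rho k_BT + 0.101\,A\rho^2$ the measured pressure of the
  pure-A fluid sits about $5\%$ low (the acceptance script reports the
  ratio) — the equation-of-state coefficient is itself an approximate
  fit, and its overestimate at these parameters is a property of the
  estimate, not of the integrator.
* Problem sizes in the tests and the acceptance script are reduced-scale
  choices: fluids of 3,000 beads, dissolution boxes of ~13,000 beads, and
  schedules of $10^3$–$10^4$ steps, which keep a full run in minutes while
  leaving every property measurable.

## Known limitations

* No electrostatics (by design: the parametrization encodes hydration in
  the repulsion table), no angle/dihedral terms, no barostat, no GPU.
* Quantitative diffusion constants comparable to the published tables
  require full-scale boxes and long stochastic schedules; at reduced
  scale the package demonstrates directions of effect and exact analytic
  identities instead.
* The wall functional form and the compartment equations were
  reconstructed from their stated semantics (quadratic repulsion;
  first-order transformation feeding a Fickian chain); both are documented
  choices with configurable constants.
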