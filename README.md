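# dpdiss

Dissipative particle dynamics (DPD) of dissolving surfactant lamellar
phases, in R with a compiled core.

When a concentrated surfactant paste meets water — in a washing machine, a
formulation plant, a capillary experiment — the lamellar phase at the
interface breaks up layer by layer into spherical micelles that then
diffuse away. `dpdiss` is for researchers who want to simulate and analyse
that process at the mesoscale: it provides a full NVT DPD engine for
bead-spring amphiphiles (six-bead anionic surfactants `3A2BC` = AAABBC and
`4ABC` = AAAABC, water beads lumping four molecules, oil chains of 1–4
beads), the two-stage dissolution experiment (equilibrate an 80 vol%
lamellar box; rotate, crop, stitch to a water column behind repulsive
walls; relax with restrained head groups; dissolve), and the analysis
stack used to quantify the outcome.

The physics in brief: beads interact through a soft conservative repulsion
`F^C = A_ij (1 − r/r_c) r̂` plus a dissipative/random pair
(`ω_D = ω_R² = (1 − r/r_c)²`, `σ² = 2γk_BT`) forming a momentum-conserving
thermostat; bonds are harmonic springs `κ = 75`, `r_eq = 0.45`; integration
is Groot–Warren modified velocity-Verlet (`λ = ½`, `Δt = 0.02`) at density
`ρ = 3` in reduced units. Analyses include concentration profiles along
the dissolution axis (bins of 0.332 r_c) with the standard deviation of
concentration as homogeneity metric, micelle detection by single-linkage
clustering of chains over their hydrophobic beads (clusters of ≤ 3 chains
count as free surfactant), the micelle size metric `1/V^(1/3)`, and a
five-zone compartment model of dissolution — first-order transformation of
the lamellar zone (rate `k_trans`) feeding Fickian exchange (constant `D`)
between equal zones — fitted by joint Levenberg–Marquardt least squares.

## Worked example

Identify micelles in a mixed-surfactant configuration with solubilized oil
(here a planted fixture so the ground truth is known; `run_pipeline()`
produces the same objects from an actual dissolution run):

```r
library(dpdiss)
matrix <- build_interaction_matrix()   # warns: the raw A-O entry is asymmetric

g <- gen_planted_micelles(3, c("3A2BC" = 20, "4ABC" = 20),
                          box = c(24, 24, 24),
                          oil_per_cluster = 4, oil_template = "oil2", seed = 7)
mset <- find_micelles(g$state)
mset
#> <micelle_set> 3 micelle(s), 0 free chain(s) of 120 total
#>   chains per micelle: mean 40.0, range 40-40
micelle_statistics(mset)[c("mean_chains", "mean_volume", "size_metric")]
#> $mean_chains
#> [1] 40
#> $mean_volume
#> [1] 248
#> $size_metric
#> [1] 0.1591657
```

Each micelle holds 40 six-bead chains (240 beads) plus 4 two-bead oil
molecules, so the mean micelle volume is 248 bead volumes and the size
metric `V^(-1/3) = 0.159` — under Stokes–Einstein behaviour this number is
proportional to the micelle diffusion constant. The per-micelle
composition table shows both surfactants evenly mixed (fraction 0.5 each,
mixing index 0).

Fit the zonal kinetic model to noisy synthetic curves with known
parameters:

```r
ser <- gen_zonal_curves(0.02, 0.1, noise_sd = 0.01, n_points = 200,
                        t_max = 200, seed = 1)
fit_zonal_parameters(ser)
#> <zonal_fit> k_trans = 0.01947, D = 0.09835 (residual 0.37)
```

Both rates recover within a few percent of the planted (0.02, 0.1). The
physical unit mapping behind the coarse-graining:

```r
physical_units()
#> $bead_mass_kg
#> [1] 1.196603e-25
#> $r_c_m
#> [1] 7.114189e-10
```

Example YAML configurations for the seven surfactant mixtures, the four
oil chain lengths and a reduced-scale demo ship under `inst/configs/`;
`run_pipeline("<config>.yaml", seed = 1, out_dir = "out")` runs the whole
experiment and writes the trajectory (extended XYZ), homogeneity series
and zonal series with a reproducibility manifest.

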