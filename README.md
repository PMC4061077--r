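# dipolarwave

Orientational analysis of membrane-bound peptides from solid-state
¹⁹F-NMR dipolar couplings.

A CF₃ reporter side chain placed at successive positions of a
membrane-bound peptide yields one signed dipolar splitting per labelled
site in a macroscopically oriented lipid bilayer. For an α-helix those
splittings trace a sinusoid-like *dipolar wave* along the sequence,

Δν(θ) = Δν_max · P₂(cos θ),   cos θᵢ = cos τ cos α + sin τ sin α cos(φᵢ − ρ),

where τ is the helix tilt from the membrane normal, ρ the azimuthal
rotation about the helix axis, (α = 121.1°, β = 53.2°) the
Cα–Cβ bond orientation of the CF₃-Bpg side chain in the helix frame,
and φᵢ the wheel azimuth of residue i (100° per residue). `dipolarwave`
implements

* the geometric forward model with Gaussian dynamic averaging
  (σ_τ, σ_ρ), the −1/2 scaling of splittings at 90° sample tilt, and
  the −Δν_max/2 powder edge of immobilized peptide;
* exhaustive least-squares fitting of (τ, ρ, σ_τ, σ_ρ) with full RMSD
  landscapes, degenerate-solution reporting (including the exact
  mirror solution 180°−τ, ρ+180°), and segmental analysis for
  bipartite peptides;
* per-site conformational-state classification — mobile vs.
  immobilized from the 0°/90° pair, in-plane unstructured (+7 kHz
  signature) vs. helical, and aggregation-prone positions from powder
  components;
* a synthetic coupling generator that reproduces the statistical
  structure of the experimental tables (noise sd 0.5 kHz), so the
  whole pipeline is testable end to end;
* helical-wheel projection, ideal-helix coordinate building and PDB
  export, TSV/CSV/JSON/YAML readers and writers.

The worked analysis ships for TP10 (`AGYLLGKINLKALAALAKKIL`), a
21-residue chimeric cell-penetrating peptide whose galanin-derived
N-terminus is intrinsically unstructured in the membrane plane while
its mastoparan-derived C-terminal helix sits in the bilayer at an
oblique tilt.

## Worked example

```r
library(dipolarwave)

## monomer coupling table (synthetic reconstruction, both sample tilts)
m <- make_tp10_fixture("L_monomer_1to400", noise_sd = 0)

## a straight helix through all nine labels fails ...
fit_orientation(m)$solution$rmsd
#> [1] 4.265   # kHz -- far above the 0.5 kHz experimental error

## ... but the segmental analysis solves the bipartite structure
seg <- segmental_fit(m)
seg$N_terminal$verdict
#> [1] "unstructured"
seg$C_terminal$solution
#> orientation solution (5 labels, 10 couplings)
#>   tau = 55.0 deg, rho = 120.0 deg
#>   sigma_tau = 0.0 deg, sigma_rho = 16.0 deg
#>   RMSD = 0.000 kHz; 2 grid cell(s) in degenerate set

## aggregation scan of the D-epimer series at high concentration
d <- make_tp10_fixture("D_highconc_1to50", noise_sd = 0.5, seed = 1)
scan_states(d)$summary
#>   epimer pl_ratio n_aggregated aggregated_positions
#> 1      D     1:50            4          13,16,20,21
```

The C-terminal helix comes out tilted at τ ≈ 55° with ρ ≈ 120° (RMSD
≈ 0 on the reconstruction; ~0.5 kHz on noisy data), the N-terminal
labels sit uniformly at the +7 kHz in-plane unstructured signature,
and exactly the four C-terminal D-substitution sites (Leu13, Leu16,
Ile20, Leu21) are flagged aggregation-prone — the published TP10
picture.

## Analysis workflow

The `analysis/` scripts run the full study over synthetic datasets and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # generate the three datasets
Rscript analysis/02_fit_monomer.R       # dipolar-wave fit + landscapes
Rscript analysis/03_scan_aggregation.R  # D-epimer positional scan
Rscript analysis/04_structure_report.R  # wheel, PDB export, CD arithmetic
```

## Package layout

* `R/` — geometry, forward model, fitting, classification, synthetic
  data, readers/writers.
* `inst/extdata/` — noiseless synthetic reference tables for the three
  TP10 scenarios (filenames carry `_synthetic`).
* `vignettes/tp10-orientational-analysis.Rmd` — the model, its
  assumptions, numerical choices and limitations.
* `tests/testthat/` — unit, property and end-to-end tests.
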