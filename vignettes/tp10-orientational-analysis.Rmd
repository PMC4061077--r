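---
title: "Solving membrane-bound peptide orientation from CF3 dipolar couplings"
author: "dipolarwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving membrane-bound peptide orientation from CF3 dipolar couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolarwave)
```

## The measurement and the model

A trifluoromethyl (CF3) reporter group placed on a rigid side chain of a
membrane-bound peptide produces, in a macroscopically oriented lipid
bilayer sample, a single signed dipolar splitting per labelled position.
For a CF3 group rotating about its own axis the splitting depends only
on the angle $\theta$ between the C$_\alpha$–C$_\beta$ bond and the
magnetic field:

$$\Delta\nu(\theta) = \Delta\nu_\max \, P_2(\cos\theta), \qquad
P_2(x) = \tfrac{1}{2}(3x^2 - 1).$$

When the sample normal is parallel to the field (0° tilt) and the
backbone is an ideal $\alpha$-helix, $\theta$ is fixed by four angles:
the helix tilt $\tau$ from the membrane normal, the azimuthal rotation
$\rho$ of the helix about its own axis, and the side-chain bond
orientation in the helix frame, described by a polar angle
$\alpha = 121.1°$ from the helix axis and an azimuthal offset
$\beta = 53.2°$ from the residue's radial direction on the helical
wheel (the established values for the CF3-Bpg side chain):

$$\cos\theta_i = \cos\tau\cos\alpha +
  \sin\tau\sin\alpha\,\cos(\phi_i - \rho), \qquad
  \phi_i = -100° \cdot (i - i_\mathrm{ref}) + \beta .$$

Marching the label along the sequence samples $\phi_i$ in 100° steps,
so the predicted splittings trace a sinusoid-like *dipolar wave* with a
period of 3.6 residues. Its amplitude and phase encode $\tau$ and
$\rho$; fitting the wave to a handful of labelled positions solves the
orientation.

Sign convention (the experiment determines $\phi_i$ only up to a
handedness, so one self-consistent convention must be fixed): for the
right-handed $\alpha$-helix viewed from the N-terminus the wheel
azimuth *decreases* by 100° per residue going N→C, and increasing
$\rho$ rotates the wheel counterclockwise in that view. With this
choice the fitted TP10 solution places the lysines of the C-terminal
helix on the aqueous side, as the amphiphilic profile demands.

## Motional averaging

Whole-body motion of the peptide is modelled by independent Gaussian
distributions of the tilt, $\tau' \sim N(\tau, \sigma_\tau)$, and of
the azimuthal rotation, $\rho' \sim N(\rho, \sigma_\rho)$. The observed
splitting is the average of $\Delta\nu_\max P_2(\cos\theta)$ over both.

Because $P_2(\cos\theta(\rho'))$ is a second-order Fourier series in
$\rho'$, the azimuthal average has a closed form: writing
$A = \cos\tau'\cos\alpha$, $B = \sin\tau'\sin\alpha$ and
$u = \phi_i - \rho'$,

$$P_2(A + B\cos u) =
  \Big[\tfrac{3A^2-1}{2} + \tfrac{3}{4}B^2\Big]
  + 3AB\cos u + \tfrac{3}{4}B^2\cos 2u,$$

and the Gaussian average of $\cos ku$ is
$e^{-k^2\sigma_\rho^2/2}\cos k(\phi_i-\rho)$. Only the tilt average is
evaluated numerically, with a 41-node Gauss–Hermite rule (exact
Gaussian weight, no truncation). We chose this hybrid over a brute
two-dimensional quadrature grid deliberately: a fixed-width grid in
$\rho'$ aliases against the 360° periodicity of the integrand once
$\sigma_\rho$ spans several turns, whereas the closed form is exact for
every $\sigma_\rho$ and reproduces the uniform-azimuth limit
$\Delta\nu_\max P_2(\cos\tau)P_2(\cos\alpha)$ (spherical-harmonic
addition theorem) by construction. The test suite verifies the hybrid
against an independent plain Monte-Carlo average of the static model to
within 0.01 kHz over random parameter draws.

Two empirical reference values complete the model. The rigid-limit
constant is set to $\Delta\nu_\max = 16$ kHz, calibrated so that the
dominant 90°-edge of a static uniaxial powder pattern,
$-\Delta\nu_\max/2$, equals the $-8$ kHz splitting observed for
immobilized aggregates. A backbone that is intrinsically unstructured
and flexibly averaging within the membrane plane shows a uniform
splitting of about $+7$ kHz; this is carried as an empirical constant,
not derived from a motional model.

## Sample tilt and mobility

Each oriented sample is measured twice, with the bilayer normal
parallel (0°) and perpendicular (90°) to the field. A peptide in fast
rotational diffusion about the membrane normal scales every splitting
by exactly $-1/2$ at 90°; an immobilized peptide does not. This gives
a per-site mobility test (`mobility_call`, tolerance 1.0 kHz = twice
the 0.5 kHz experimental coupling error) and doubles the data for the
orientational fit, since 90° rows can be compared against the scaled
prediction without new parameters.

## Least-squares fitting and degeneracy

`fit_orientation` minimizes the sum of squared deviations between
measured and predicted couplings over an exhaustive grid: $\tau$ in
0–180° and $\rho$ in 0–359° at 1° steps, $\sigma_\tau$ and
$\sigma_\rho$ in 0–30° at 2° steps. The reported landscape holds, at
each $(\tau, \rho)$, the RMSD minimized over both $\sigma$ grids — the
choice matters because the published contour plots do not state it, and
minimizing over the dynamics shows the orientational degeneracy
honestly rather than at one arbitrary wobble. RMSD (kHz) is reported
instead of the raw sum of squares; the argmin is identical.

Degeneracy is a physical feature here, not a numerical nuisance:

* $P_2$ is even, so the mirror orientation $(180° - \tau, \rho + 180°)$
  predicts *identical* couplings for every site. Both branches are
  always reported; the canonical solution is the grid argmin with
  floating-point ties broken toward the smaller $\tau$.
* With azimuthal wobble in the data, the $\tau$ valley is genuinely
  flat over several degrees (larger $\sigma_\rho$ trades against
  smaller $\tau$). All grid cells within 0.01 kHz of the minimum are
  returned as `degenerate_set` — the machine-readable form of the
  "possible range of $\tau$ and $\rho$ with the same RMSD". We
  deliberately report the argmin rather than an extreme cell of the
  tie set as the canonical answer, because the tie set is asymmetric
  around the valley bottom and an extreme-cell rule biases $\tau$ low.
* A single measurement constrains one angle combination only; the fit
  then warns and returns the full degenerate band.

The floating-point tie tolerance (1e-6 kHz) sits above the rounding
floor of the expanded sum-of-squares accumulation and far below any
physically meaningful RMSD difference.

`segmental_fit` applies the same machinery per segment. A segment
whose best RMSD exceeds 1.0 kHz (twice the experimental error) rejects
the straight-helix model; if in addition the per-site means of its
0°-equivalent couplings (90° rows unscaled by $-2$; the per-site mean
halves the doubled noise of unscaled single rows) all lie within
1.5 kHz of the $+7$ kHz reference, the segment is classified as
in-plane unstructured instead.

## Conformational-state scan

`scan_states` combines the pieces per labelled site: mobility from the
0°/90° pair; for mobile sites, the unstructured reference test and
joint helix membership; for sites with a powder component at the
$-8$ kHz edge, the verdict `aggregated_beta_candidate` — "candidate"
because the powder pattern proves immobilization and loss of
orientational order, not $\beta$-sheet conformation (that confirmation
requires independent spectroscopy and is out of scope here). A site
showing both a sharp mobile component and a powder component is
reported as partly aggregated through two evidence entries on one
call, mirroring superimposed spectral components.

## The synthetic data generator

No public archive carries the experimental coupling tables, so the
generator reproduces their statistical structure and stands in for
them everywhere: helical segments get forward-model splittings,
unstructured segments the $+7$ kHz reference, aggregated segments the
powder edge with the powder flag set (identical at both tilts, without
added noise — the powder edge is a lineshape feature, not a resolved
splitting). Mobile rows receive i.i.d. Gaussian noise of sd 0.5 kHz —
the stated experimental error — after tilt scaling.

The TP10 study conditions are frozen in `make_tp10_fixture`:

* `L_monomer_1to400` — labels Gly2–Ile8 unstructured; Leu10–Leu21
  helical at $\tau = 55°$, $\rho = 120°$. The published analysis
  reports a moderate wobble about the long axis and no tilt wobble, so
  the fixture uses $\sigma_\tau = 0$ and $\sigma_\rho = 16°$; 16° is
  moderate on the 0–30° scale and lies on the $\sigma$ search grid, so
  the noiseless table round-trips through the fitter exactly.
* `D_lowconc_1to400` — every site unstructured (a single D-amino acid
  unfolds the helix in the membrane plane).
* `D_highconc_1to50` — Gly2–Leu10 mobile and unstructured, Leu13,
  Leu16, Ile20 and Leu21 aggregated. Leu10 sides with the flexible
  part in both this scenario and the monomer segment map, where it is
  the first residue of the fitted C-terminal helix.

What the synthetic data do *not* emulate: correlated noise between
sites or tilts, partial powder fractions with quantitative intensity
ratios, lipid-signal quality controls, and any ageing kinetics of
aggregation. Passing the pipeline tests therefore demonstrates that
the analysis recovers the states and angles it assumes generated the
data — it does not validate the geometric conventions against an
independent experimental structure.

## Numerical choices and problem sizes

* All interfaces use degrees and kHz; radians exist only inside
  trigonometric evaluation.
* The full four-parameter grid (181 × 360 × 16 × 16) evaluates in
  about a second per fit through the per-site Fourier collapse of the
  sum of squares; an optional bounded quasi-Newton refinement
  (`refine = TRUE`) polishes below grid resolution.
* The parameter-recovery study in the test suite uses 50 random
  orientations with 5 labels at both tilts and noise sd 0.5 kHz
  (generated without wobble, so the recovery errors measure
  orientation information only); median recovery is about 1° in
  $\tau$ and 1–2° in $\rho$, comfortably inside the 5°/10° bounds the
  tests assert, with the mirror branch counted as recovered.
* The Monte-Carlo cross-check of the forward model uses antithetic
  Gaussian sampling (4 × 10^6 evaluations per draw) to push the
  oracle's own error safely below the 0.01 kHz agreement bound.

## Worked example

```{r example, eval = FALSE}
library(dipolarwave)

## reconstructed monomer table (noiseless reference; a noisy
## realisation is one argument away)
m <- make_tp10_fixture("L_monomer_1to400", noise_sd = 0)

seg <- segmental_fit(m)
seg$C_terminal$solution
#> orientation solution (5 labels, 10 couplings)
#>   tau = 55.0 deg, rho = 120.0 deg
#>   sigma_tau = 0.0 deg, sigma_rho = 16.0 deg
#>   RMSD = 0.000 kHz; 2 grid cell(s) in degenerate set
seg$N_terminal$verdict
#> [1] "unstructured"

## aggregation scan of the high-concentration D-epimer series
d <- make_tp10_fixture("D_highconc_1to50", noise_sd = 0.5, seed = 1)
scan_states(d)$summary$aggregated_positions
#> [1] "13,16,20,21"
```

## Known limitations

* The helix is ideal and straight; a kinked peptide is handled by
  segmental fitting, not by a jointly kinked model.
* Grid degeneracy stands in for error bars; there is no bootstrap or
  profile likelihood.
* The $(\alpha, \beta)$ convention for the side-chain bond is taken as
  polar-angle-plus-azimuthal-offset; this interpretation is validated
  internally by the round-trip and amphiphilicity checks, which is the
  strongest validation available without an independent structure.
* The $\beta$-sheet identity of aggregated sites is a candidate call
  only.
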