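---
title: "Predicting water 17O chemical shifts from hydrogen-bond geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting water 17O chemical shifts from hydrogen-bond geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquashift)
```

## The model

The ¹⁷O chemical shift of a water molecule is dominated by its
hydrogen bonding.  This package implements an empirical model in which
each hydrogen bond contributes a deshielding that depends only on the
hydrogen-bond distance `r` — the distance between the donated H atom
and the acceptor oxygen — and on the role the water plays in the bond:

* **acceptor** (another molecule's H points at this water's O):
  `137.08 / r⁴` ppm,
* **donor** (this water donates one of its own H atoms):
  `60.98 / r⁴` ppm.

The acceptor effect is roughly twice the donor effect.  The `1/r⁴`
form vanishes at infinite separation, which makes the isolated water
molecule the natural reference state: all shifts are deshieldings in
ppm relative to an isolated H₂O, and `rereference_to_bulk()` converts
to the bulk-water scale by subtracting the 36.1 ppm gas-to-liquid
shift.  Angular dependence is deliberately ignored: over the relevant
range of hydrogen-bond angles the shift changes by only 1–2 ppm, while
the distance dependence is steep.

Per-bond contributions are additive to good approximation, so the raw
prediction for a water with several bonds is a sum of per-bond terms.
Because a dimer-derived function underestimates cooperative effects in
larger clusters — mainly the additional stretching of the covalent O–H
bonds — the raw sum `S` is mapped through a linear calibration fitted
against cluster-level ab initio shifts, with the two bonding regimes
separated:

* no dangling O–H (water donates two bonds): `δ = 1.38·S − 0.78`,
* dangling O–H (water donates fewer than two): `δ = 1.20·S − 0.64`.

An alternative formulation accounts for covalent-bond stretch
explicitly: `bond_length_correction()` adds
`(579.36/2)·(r_OH − 0.962)` ppm per covalent bond (half the
simultaneous-stretch derivative of −579.36 ppm/Å, since that printed
derivative moves both bonds together), after which the calibration
slopes drop to 1.12 (no dangling) and 0.95 (dangling) with no
intercept.  A single global calibration (1.43/−4.05, or 1.05/0.08 with
the bond-length correction) and the unrelaxed dimer slopes (120/40
ppm·Å⁴) are selectable through `shift_params(variant = ...)` but are
not defaults.

Solute partners extend the model:

* **DMSO**: donation to the S=O oxygen contributes `270.49 / r⁶` and
  each CH···O methyl contact `1799.10 / r⁶` ppm.  These coefficients
  descend from the water–methane model slope 1694.2 ppm·Å⁶ through the
  conformer scalings 1.13 and 0.94; the printed equation coefficients
  are used verbatim rather than the re-derived products
  (1694.2·1.13·0.94 ≈ 1799.5 vs the printed 1799.10), since the
  composed equation is the calibrated object.
* **glycerol**: hydroxyl groups donate and accept with the water–water
  functions scaled by 0.9 per bond inside the calibration braces;
  glycerol C–H groups use the same CH···O term as DMSO.  Shifts are
  predicted for water oxygens only.

## Hydrogen-bond criteria

`detect_hbonds()` uses distance-and-angle criteria in the tradition of
Luzar and Chandler: H···O distance < 2.5 Å (first solvation shell) and
O–H···O angle > 150°.  The angular criterion can be disabled
(`use_angle = FALSE`) because the cluster-level analysis that produced
the calibrations is naturally keyed on the 2.5 Å distance criterion
alone; both behaviours are exposed and neither is treated as uniquely
canonical.  CH···O contacts (`detect_ch_contacts()`) have no angular
criterion and use a 3.0 Å cutoff — no cutoff is inherited from the
source analyses, and 3.0 Å comfortably contains the DMSO conformer
geometries while excluding second-shell contacts.

Classification is per water: `dangling` means fewer than two donated
bonds, so zero-donor waters also use the dangling calibration (they
possess free O–H bonds, which is the closer physical regime).
Donations to DMSO or glycerol acceptors count toward the dangling
determination even though the DMSO bond itself is modelled outside the
water–water calibration.

## Composition choices

Several composition questions were genuinely open and are resolved as
follows:

* **Zero-bond waters return 0 ppm**, not the negative calibration
  intercepts: the calibrations are fits over hydrogen-bonded sites and
  extrapolating them to an empty bond set would contradict the
  isolated-molecule reference.  By the same logic, the scale/intercept
  map is applied **only when the water/glycerol raw sum has at least
  one contributing bond**; a water whose only interactions are with
  DMSO (e.g. the Conf1 complex) receives the independently calibrated
  r⁻⁶ terms with no water–water intercept attached, which reproduces
  the DMSO equation exactly.
* **DMSO and CH···O terms are added outside the calibration braces.**
  Each of those terms carries its own calibration (the conformer
  scaling factors), and nesting them inside the water–water
  scale/intercept would double-calibrate them.
* **The glycerol 0.9 factor applies per bond inside the braces**, i.e.
  the bond's r⁻⁴ term is scaled before the sum is calibrated.
* **Bond-length reference**: the correction is measured from the free
  O–H length 0.962 Å for every covalent bond, including donated ones.

## The synthetic-structure generator

The generators are constructive: every requested geometric parameter
is exact on the output (verified to 1e-9 Å and 1e-7 degrees in the
tests), so they serve as ground truth for the detector and the model.

* `make_dimer()` defaults to the optimised dimer geometry: H···O
  1.71 Å, O–H···O 163.7°, H···O–H 109.6°, donated O–H stretched to
  0.968 Å and free O–H 0.962 Å.
* The internal H–O–H angle defaults to 104.5°.  The optimised value is
  not printed in the source analyses; since the shift is insensitive
  to this angle (~1 ppm over 10°), the standard textbook value is used
  and the choice is immaterial.
* `make_multimer()` arranges neighbours tetrahedrally around a central
  water (donated bonds along the O–H directions, accepted bonds along
  lone-pair directions), orients partners with the dimer angles, and
  verifies with the detector that exactly the requested topology is
  realised, re-trying with seeded perturbed azimuths otherwise.
* `make_dmso_water()` builds simplified rigid DMSO·H₂O complexes whose
  interaction patterns match the three reference conformers; contact
  C–H bonds are collinear with the water oxygen so that requested
  distances are exact.  The toy glycerol is a full C₃H₈O₃ scaffold
  with schematic internal geometry whose end hydroxyl is the
  hydrogen-bonding group.
* `perturb_trajectory()` emulates MD snapshots by Gaussian atomic
  displacement with covalent X–H bond lengths re-projected to their
  original values.

These fixtures emulate hydrogen-bond topology and distance/angle
distributions, not force-field energetics: there is no excluded-volume
realism, no cooperative polarisation, and no Boltzmann weighting.
Passing tests therefore demonstrate that the implementation evaluates
the model correctly, not that the model reproduces ab initio shifts
for arbitrary real configurations — the latter claim rests on the
published calibration fits whose raw scan data are not reproducible
here.

## Numerical choices

* Covalent connectivity uses pairwise cutoffs O–H 1.2, C–H 1.3, S–O
  1.7, C–C 1.7, C–O 1.7 and S–C 1.9 Å; an H within covalent range of
  two heavy atoms is an error (ambiguous assignment), and unknown
  formulas degrade to kind `other` with a warning.
* All criteria are strict inequalities (`r < r_max`,
  `angle > angle_min`); distances are plain Euclidean with no periodic
  boundaries (clusters and hydrate fragments only).
* Through-origin fits report R² against the uncentered sum of squares;
  the convention is stated in the fit object's print method.
* Fixture coordinates are written with 6 decimals; the round-trip
  tests assert at that precision.
* Problem sizes in the test-suite property checks — 1,000 randomized
  profiles for the model oracle, 100 random clusters of up to 20
  waters for the detector oracle, 50 constructive round trips, 100
  noisy fit replicates — were chosen to exercise every code path and
  branch combination while keeping the default suite under a minute.

## Limitations

* The model covers water ¹⁷O only, with water, DMSO (S=O and methyl)
  and glycerol (hydroxyl and C–H) partners.  Carbonyl or N–H partners
  are out of scope; the source analyses indicate the water-derived
  functions may not transfer to them.
* Quantum-chemical quantities (the 326.14 ppm reference shielding, the
  −579.36 ppm/Å derivative, the cluster shift tables, the scan data
  behind the fitted slopes) enter as fixed constants and are not
  recomputable by this package.
* Binary trajectory formats (DCD/XTC) and periodic-boundary unwrapping
  are unsupported; multi-frame input is XYZ blocks or PDB MODEL
  records with identical atom counts.

## A worked example

```{r}
sys <- make_multimer(topology_spec(2, 2, distances = 1.70))
profile_waters(sys)[[1]]
calibrated_water_shift(profile_waters(sys)[[1]])
```

```{r}
res <- run_predict(sys, reference = "bulk")
res$table[, c("water", "n_accepted", "n_donated", "dangling", "shift")]
```
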