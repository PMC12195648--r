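---
title: "Field-based 3D-QSAR with fieldqsar: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR with fieldqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldqsar)
```

## The modelling problem

Congeneric small-molecule series — a common scaffold decorated with varying
substituents, such as the 2,6,9-trisubstituted purines studied as Bcr-Abl
kinase inhibitors — often show activity differences that are governed by
*where* bulk, charge or hydrophobicity sits in space rather than by any
whole-molecule descriptor. Field-based 3D-QSAR makes that explicit: every
compound, rigidly superimposed onto the series' common frame, is described
by probe interaction values sampled on a shared rectilinear lattice, and
activity is regressed on those thousands of collinear grid descriptors by
partial least squares (PLS).

`fieldqsar` implements that full analysis stage. Three inputs are assumed,
and deliberately not computed here: 3D conformers (one per compound),
their superposition, and per-atom partial charges. All three are scientific
choices with their own tooling; treating them as inputs keeps the model
auditable.

## Fields

Two families of descriptors are available on the lattice (default spacing
2 Å, default margin 4 Å beyond the union bounding box):

* **Interaction energies** (`method = "comfa"`). Steric: Lennard-Jones 6-12
  with arithmetically combined radii (sp³-carbon probe, radius 1.52 Å) and
  geometric-mean well depths; a uniform atom well depth of 0.1 kcal/mol is
  the default and is editable in `field_config()`, since published grid-field
  studies inherit these constants from proprietary force-field tables without
  printing them. Electrostatic: Coulomb with distance-dependent dielectric
  `D(r) = r` and prefactor 332.0636 kcal·Å/(mol·e²). Both are truncated at
  ±30 kcal/mol, the conventional cutoff; the truncation also absorbs the
  `r → 0` singularity (numerically, squared distances are floored at
  10⁻⁴ Ų, far beyond the cap).
* **Similarity indices** (`method = "comsia"`). Gaussian-attenuated sums
  `−Σ w_probe w_ik exp(−α r²)` with α = 0.3 Å⁻² for five properties:
  steric (atom weight = r_vdw³), electrostatic (partial charge),
  hydrophobic, donor and acceptor (element-typed weights from
  `atom_typing()`, a deliberately coarse, user-editable table). The sign
  convention is fixed by the single-atom test value of −1 at zero distance
  for unit weights; no cutoff is needed because the Gaussian decays.

Grid points buried inside a molecule carry a capped steric value, and the
Coulomb value there is physically meaningless; following the conventional
treatment, the assembled matrix replaces those electrostatic entries by the
column mean over the uncapped compounds (`electrostatic_fill` switches this
off).

## Column filtering and block scaling

Columns whose standard deviation across compounds falls below
`column_filter_sigma` (default 2.0, in the column's own units — kcal/mol
for energy blocks) are masked from modelling but kept for contour export.
We interpret the published "column filter 2.0" as this minimum-variation
threshold on plain column standard deviations; whether the original
software applied it before or after internal scaling is not recoverable
from typical methods sections, and the plain-units reading is the one that
matches hand-checkable examples. For dimensionless similarity blocks the
same sigma is usually too aggressive; `column_filter()` therefore accepts a
named per-block vector (e.g. `c(comsia_H = 0.3)`).

Before PLS, each field block is divided by the standard deviation of its
centred entries, so no block dominates by units alone; the factors are
recorded and undone when coefficients are reported in raw units.

## PLS, cross-validation and model search

Components are extracted by the NIPALS recursion on the centred,
block-scaled, filter-retained matrix. The test suite pins the
implementation against an independent Krylov-subspace formulation of
univariate PLS and against ordinary least squares at full rank.

* **q²** is computed by *exact* leave-one-out: each compound is held out,
  centring refit on the remainder, and
  `q² = 1 − PRESS / Σ(y_i − ȳ)²` with ȳ the full-set mean. SAMPLS-style
  acceleration is unnecessary at these set sizes (tens of compounds) and is
  not implemented, so no SAMPLS-equivalence is claimed.
* **N** (number of components) is selected to maximise q², ties broken
  toward the smaller model; the full q²-vs-N profile is always returned
  because a flat profile is itself diagnostic.
* **SEE** is `sqrt(RSS / (n − N − 1))`, the convention of the major
  commercial implementation; published tables rarely define it, so the
  choice is documented here.
* `model_search()` fits every non-empty subset of the enabled field blocks
  and ranks by q² — the standard "successive field combinations" table
  (fields, q², N, SEE, r², per-field contribution percentages).

Degenerate inputs fail loudly: constant activity vectors, component counts
outside `[1, min(n − 1, p)]`, and empty post-filter matrices are errors,
and rank exhaustion inside NIPALS truncates with a warning.

## Validation battery

`external_metrics()` + `gt_conditions()` evaluate, on a held-out test set
of at least three compounds: q² > 0.5; r²test > 0.6;
`(r²test − r²₀)/r²test < 0.1` (or the primed analogue); through-origin
slope k or k′ in [0.85, 1.15]; `|r²₀ − r′²₀| < 0.3`; and Roy's
`r²m = r²test (1 − √(r²test − r²₀)) > 0.5`. The square root uses the
absolute difference when r²₀ exceeds r²test — typeset versions of the
formula are frequently garbled, and this is the standard reading. The
overall verdict uses the correlation/slope conditions; the r²m check is
reported as its own flag, since the literature is inconsistent about
whether it belongs to the same numbered battery.

`y_randomization()` permutes the response (seeded, default 50 iterations —
published studies typically say only "several"), refits with the original
component count, and passes when every scrambled model has q² < 0.5 and
r²ncv < 0.6. Prediction outliers are flagged at |residual| > 1.0 log unit,
strictly: a residual of exactly one log unit is not an outlier, a boundary
decision made explicit in the tests.

## Applicability domain

The standardization approach: per-descriptor training means and *sample*
(n−1) standard deviations (the source method does not specify population
versus sample; sample is used consistently and the choice is switchable in
code), standardized absolute deviations `S_ik` per query compound, then
inside iff `max(S) ≤ 3`, outside iff `min(S) > 3`, and at the border
`S_new = mean(S) + 1.28 sd(S) ≤ 3` decides. The incomplete sentence that
usually accompanies this rule in print ("must fulfil the condition
S_new = ...") is resolved against the cited source method as the ≤ 3
comparison.

By default the assessment runs in the PLS latent-score space:
standardizing thousands of near-duplicate grid columns is degenerate
(constant columns drop, near-constant ones explode), whereas the score
space is exactly the geometry the model predicts from. A raw-descriptor
mode exists for explicit descriptor tables.

## Druglikeness screening

`lipinski()` (MW ≤ 500, HBD ≤ 5, HBA ≤ 10, cLogP ≤ 5; boundary compliant;
classic pass allows one violation), `veber()` (TPSA ≤ 140 Ų, rotatable
bonds ≤ 10) and a six-axis bioavailability-radar range check. Descriptors
are *inputs*: property-prediction engines differ, so which cLogP or TPSA
is screened is the caller's decision, not silently re-derived here.

## The synthetic generator

`synthetic_series()` is first-class, tested code, not a fixture. It
emulates what a grid-field model legitimately assumes: a rigid planar
purine-like bicycle (identical coordinates in every compound — perfect
superposition), three substituent sites mimicking 2-/6-/9-substitution
whose atom properties (radius 1.2–2.2 Å, charge ±0.5 e, property weights)
vary per compound while positions stay fixed. Activity is a planted
*linear function of the assembled field descriptors themselves* at
designated lattice points — steric features in the shell where the
Lennard-Jones wall sweeps as radii vary, electrostatic features farther
out where neither the cap nor the buried-point fill engages — affinely
calibrated to span pIC50 4.0–7.8, the range typical of published
kinase-inhibitor series, plus Gaussian noise (default 0.3 log units, a
realistic assay-reproducibility figure). Because the response is linear in
descriptors the pipeline itself computes, PLS-on-fields is the correctly
specified estimator, and recovery of q², external validity and contour
location are meaningful checks rather than tautologies.

What it does **not** emulate: real substituent chemistry (multi-atom
groups, conformational flexibility), alignment error (available separately
and deliberately, via `perturb_alignment()`, as a negative control),
charge-model disagreement, activity cliffs or interaction terms. Passing
tests therefore demonstrate that the statistical machinery recovers a
recoverable signal under the model's own assumptions — not that any real
series satisfies those assumptions.

Default study conditions mirror a realistic series: 58 compounds, 80/20
activity-stratified train/test split, noise 0.3. The test suite exercises
ten seeds at this scale (about a second per seed on one core), which keeps
the whole suite under a minute; smaller 16–24-compound series are used for
unit-level checks.

## Contours

`contour_grid()` thresholds the per-column product of the (scaled-space)
PLS coefficient and the column standard deviation at the 80th/20th
percentiles within each field block — common practice where no percentile
is ever printed; both are configurable. "Favoured" means activity
increases as the field value there increases. The synthetic ground truth
defines the planted beneficial region as the designated probe shell
(within 2.2 Å, about one grid spacing) of positive-steric substituent
atoms, and `contour_recovery()` reports the Jaccard overlap with the
favoured steric contour, restricted to filter-retained columns since only
modelled points can appear in a contour.

## Known limitations

* Numerical reproduction of any particular commercial implementation is a
  non-goal: force-field constants, charge models and internal scalings
  differ, so q²/r² values are comparable in kind, not in digit.
* The SDF reader requires well-formed V2000 records with bonds (bond-less
  records are rejected by the underlying parser); partial charges travel in
  a `PARTIAL_CHARGES` data field because the V2000 charge block is
  integer-only.
* Exact LOO scales quadratically with the number of compounds; at hundreds
  of compounds a grouped or SAMPLS-style CV would be preferable.
* The applicability domain is the standardization rule only; leverage /
  Williams-plot diagnostics are out of scope.
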