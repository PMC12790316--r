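---
title: "Methods: descriptors, model and screening workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, model and screening workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2screen)
```

## The problem and the model

Base-mediated C–H carboxylation proceeds through a carbanion that attacks
CO₂. Whether the resulting carboxylate is thermodynamically stable is
decided by the Gibbs free reaction energy of the addition step; we work
with its negative, the CO₂ affinity `CO2A` in kcal/mol, so that positive
values mean a stable adduct. `co2screen` restricts itself to the
nucleophilic pattern of a carbanionic carbon CA (formal charge −1) with
exactly two carbon neighbors C1 and C2 — the pattern is detected
structurally from the molecular graph, ambiguous cases (several candidate
CA sites) are rejected rather than auto-resolved.

`CO2A` is modeled by ordinary least squares on three physical-organic
descriptors: the HOMO energy ε_HOMO (Hartree), the magnitude of the
Hirshfeld atomic dipole at CA (atomic units), and the buried Sterimol B1
at CA (Å). Free energies themselves are *consumed* from an
electronic-structure backend, never re-derived: vibrational/RRHO
thermochemistry is engine territory, and the package only combines
backend Gibbs energies into reaction energies
(`co2_affinity()`, using 1 Hartree = 627.509474 kcal/mol, defined at a
single site).

The modeling assumptions are the usual linear-QSPR ones: descriptors
capture the stabilizing effects additively, training and application
domains overlap, and conformer ensembles are representative. Structural
motifs poorly described by a linear combination of these three
descriptors (e.g. unusually delocalized or internally stabilized
carbanions) are known failure modes; outliers of this kind are retained
in training by default rather than excluded, and an exclusion flag is
available for sensitivity checks.

## Conformer ensembles

Ensembles come from seeded ETKDG distance-geometry embedding with UFF
relaxation and ranking (through a bundled RDKit helper; identical inputs
and seed give bit-identical coordinates). This is a desk-scale stand-in
for metadynamics-based conformer searches: it samples torsional space
adequately for the small, semi-rigid anions targeted here, but it does
not explore ring puckering exhaustively and its force-field energies are
only a ranking device. Backend electronic energies replace them in every
downstream Boltzmann weight.

Retention parameters, all configurable:

* `n_confs = 50` — embedding attempts per molecule;
* `energy_window = 6` kcal/mol above the minimum — beyond this a
  conformer's Boltzmann weight at room temperature is below 4·10⁻⁵ and
  cannot influence an aggregated descriptor at the precision we report;
* `rmsd_threshold = 0.25` Å heavy-atom RMSD after Kabsch superposition —
  duplicates below this distance are pruned greedily from the
  energy-sorted list, which makes pruning idempotent;
* `seed = 42` — every stage seed is derived from the master seed by a
  fixed multiplicative-hash scheme, so whole runs replay exactly.

The retention settings are implementation choices (no canonical values
exist for this pipeline); their defaults were fixed once, before any
result-oriented evaluation, and the window/threshold semantics are
property-tested rather than tuned.

## Sterimol and buried Sterimol

Verloop's steric parameters are computed from van der Waals spheres about
the axis u from the attach atom toward the axis atom:

* `L = max_i( <u, x_i − x_a> + r_i )`,
* width in a perpendicular direction d: `w(d) = max_i( <d, x_i − x_a> + r_i )`,
* `B1 = min_d w(d)`, `B5 = max_d w(d)`.

The attach atom itself is the attachment point and is excluded from the
projections; with a single substituent atom on the axis this yields the
analytic values L = distance + radius and B1 = B5 = radius, which the
test suite asserts exactly. Radii default to the Bondi set (tabulated
in-code, overridable per element). L is reported without the historical
+0.40 Å CPK correction, as modern implementations do.

The direction search evaluates `w` on a 1° grid; every local extremum of
the circular grid is then refined by golden-section search to a bracket
tolerance of 10⁻¹² rad. Refining *all* local extrema (not just the global
grid winner) is what makes the result invariant under rigid motions of
the input to ~10⁻⁹ Å, since rotation shifts the grid phase and can swap
near-degenerate minima. An independent dense scan at 0.01° with no
refinement (`sterimol_scan()`) serves as the oracle; the two agree to
better than 10⁻³ Å on randomized geometries (asserted over 100 cases in
the acceptance suite, runtime well under two minutes on one CPU).

**Buried** Sterimol first discards every atom whose center lies farther
than `buried_radius` from the attach atom; the default 5.5 Å follows
common buried-descriptor conventions since no canonical value exists for
this descriptor family, and exclusion is whole-atom by center distance
(no partial sphere clipping). The axis atom is always retained so the
axis stays defined; if no other atom survives the cutoff a
degenerate-geometry error is raised. The site descriptor `site_b1()`
computes buried B1 twice — axis CA→C1 and CA→C2 — and returns the
arithmetic mean, since no combination rule is canonical for a two-axis
site; both per-axis values are preserved for inspection.

## Ensemble aggregation

`boltzmann_weights()` uses
`w_i = exp(−(E_i − E_min)/kT) / Σ_j exp(−(E_j − E_min)/kT)` with the
minimum shift for numerical stability; weights sum to 1 within 10⁻¹².
Each descriptor is aggregated four ways — min, max, Boltzmann average
(default T = 298.15 K; a 293.15 K preset exists because adduct stability
is conventionally quoted at 20 °C in DMSO), and the lowest-energy
conformer value with ties resolved to the lowest index. The invariants
min ≤ Boltz ≤ max and min ≤ lowE ≤ max, the two-state closed form at
ΔE = kT·ln 2, and the T → 0 / T → ∞ limits are all property-tested.

## Backends and parsing

A backend declares capabilities (optimize, single-point, thermochemistry,
Hirshfeld) and must populate the corresponding result fields or raise; a
capability the caller needs but the backend lacks is an error before any
compute. Results are cached content-addressed by (elements, coordinates
rounded to 10⁻⁸ Å, settings, backend, label), so identical reruns never
invoke an engine — the acceptance suite checks that a warm rerun of the
whole pipeline performs zero backend calls and reproduces the report
bit-for-bit.

Two settings presets mirror the two-round protocol: a cheap screening
level for geometries and ε_HOMO, and a refined level for affinity
energies. Both are opaque method strings passed through to engines.

Engine outputs are parsed through a dialect registry; parsers are total:
a file either yields a fully populated result or raises a typed error
naming the missing section. The HOMO is identified from orbital
occupancies (highest orbital with occupancy > 0), and the Hirshfeld site
dipole is reported as the Euclidean norm of the atomic dipole vector at
CA — the only rotation-invariant scalar of that vector; atomic units are
used throughout.

The mock backend computes smooth functions of composition and
interatomic distances only (hence rotation/translation invariant),
bit-stable across runs. Its numbers are explicitly **non-physical**; it
exists so that pipeline mechanics — caching, filtering, descriptor
assembly, failure sandboxing — can be tested without an engine, and its
pseudo-ε_HOMO is centered so that typical small carbanions fall on both
sides of the −0.140 Hartree threshold, keeping both filter branches
exercised. Passing tests on the mock therefore validate plumbing and
numerics, not chemical predictions.

## Model fitting and validation

Features are z-scored with training-split statistics only (no leakage);
coefficients are reported in standardized and raw space. Rank-deficient
feature sets raise a collinearity error naming the offending columns.
Validation follows standard practice: R² and MAE on train and test
splits, leave-one-out Q² from n full refits (the hat-matrix closed form
is used as an independent oracle in the tests, never as the
implementation), and k-fold cross-validation (k = 5) with a seeded
shuffle, fold sizes differing by at most one, and the pooled-prediction
R² reported alongside per-fold metrics.

`best_subset_search()` enumerates all feature subsets of the requested
size (default 3) below a configurable cap, skips collinear subsets with
a recorded reason, and ranks by LOO Q² with test-set MAE as tiebreak
(LOO MAE when no split is supplied). Ranking by Q² is a design choice:
among criteria computable on the training data it penalizes overfitting
most directly. The default train/test split is a seeded 75/25 random
assignment, overridable by an explicit assignment so an externally fixed
split can be reproduced exactly.

The screening threshold comparison is **inclusive**
(`ε_HOMO ≥ −0.140` Hartree passes): the boundary value proceeds to the
second round, which is the conservative direction for a pre-filter whose
purpose is to avoid discarding viable candidates. Which ensemble value
feeds the filter is configurable; the default is the lowest-energy
conformer's ε_HOMO, the most common single-conformer convention, with
the Boltzmann average as the alternative.

## Synthetic data

`simulate_descriptor_table()` emulates the statistical shape of a small
QSPR training table: n = 31 rows, three independent unit-variance true
features with planted coefficients (2, −1, 0.5), nine decoys each
correlated at 0.4 with a true feature (descriptor pools in this field are
substantially intercorrelated), and Gaussian response noise calibrated
analytically so the population R² is 0.95 — matching the performance
regime a useful three-parameter model operates in. What it does *not*
emulate: heavy-tailed descriptor distributions, heteroscedastic DFT
errors, and cluster structure from congeneric series. Recovery results
on these tables (the acceptance suite requires the planted subset to be
ranked first in ≥ 90% of 100 seeds, a sweep that runs in well under five
minutes on one CPU) therefore quantify the machinery, not real-data
performance.

Toy geometries for the Sterimol tests carry their own expected values,
computed analytically for the constructed cases or frozen from the dense
reference scan at generation time, so the tests never hard-code numbers
the generators can carry.

## Degenerate inputs and tie-breaks

* Coincident attach/axis atoms: geometry error (no axis direction).
* All substituent atoms outside the buried sphere: degenerate-geometry
  error rather than a silent B1 of the bare axis.
* Empty energy list, mismatched value/energy lengths: input errors.
* lowE ties: lowest conformer index wins (deterministic).
* Constant response: zero coefficients, intercept = mean (not an error).
* Constant nucleophilicity N in the benchmark correlation: degenerate
  error, since the slope is undefined.
* A filter survivor must carry an affinity prediction; a screened-out
  candidate never does — the invariant is enforced at row construction.

## Known limitations

* The mock backend cannot validate chemistry; quantitative predictions
  require a real engine behind the backend contract (outputs can also be
  supplied as parsed files through the directory backend).
* ETKDG/UFF ensembles may miss conformers that metadynamics would find
  for floppy or ring-flexible anions.
* The MLR is linear by construction; strongly delocalized anions are
  expected outliers.
* The Mayr nucleophilicity N is available only for kinetically
  characterized nucleophiles, so the benchmark correlation cannot enter
  the predictive model itself.

## Worked micro-example

```{r example}
g <- toy_geometry("planar-T")
sterimol(g$coords, g$radii, g$attach, g$axis)

w <- boltzmann_weights(c(0, 3.166811563e-6 * 298.15 * log(2)), 298.15)
round(w, 6)  # two-state kT*ln2 gap: 2/3 vs 1/3

tab <- simulate_descriptor_table(seed = 1)
fit <- fit_mlr(tab, attr(tab, "planted")$true_features)
round(fit$coefficients_raw, 3)
```
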