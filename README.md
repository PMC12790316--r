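# co2screen

Virtual screening of carbon-centered nucleophiles for stable CO₂
carboxylation adducts.

Base-mediated C–H carboxylation turns CO₂ into a C1 building block: a
strong base deprotonates a C–H acid and the resulting carbanion attacks
CO₂ to form a carboxylate. Because CO₂ is a deep thermodynamic sink, most
such adducts are unstable, and the practical question for a synthetic
chemist is *which* carbanions bind CO₂ exergonically. `co2screen`
implements a predictive workflow that answers this from SMILES strings
alone, for the nucleophilic pattern of a carbanionic carbon **CA**
(formal charge −1) flanked by exactly two carbon neighbors **C1**/**C2**.

The target property is the **CO₂ affinity**,

```
CO2A = −ΔG_rxn = −(G_adduct − G_nucleophile − G_CO2)   [kcal/mol]
```

so CO2A > 0 marks a thermodynamically stable adduct. CO2A is predicted by
a three-parameter multivariate linear regression on conformer-ensemble
descriptors:

```
CO2A ≈ β₀ + β₁·ε_HOMO + β₂·|μ_CA| + β₃·B1ᵇᵘʳ(CA; C1/C2)
```

* **ε_HOMO** — HOMO energy (Hartree): a higher (less negative) value means a
  more easily donated electron pair, favoring C–C bond formation with CO₂;
* **|μ_CA|** — magnitude of the Hirshfeld atomic dipole at CA (a.u.):
  electrostatic pre-organization of the attacking site;
* **B1ᵇᵘʳ** — buried Sterimol B1 at CA, averaged over the CA→C1 and CA→C2
  axes (Å): local steric bulk shielding the nascent carboxylate.

Each descriptor is collected over a conformer ensemble in four
aggregations (min, max, Boltzmann-weighted average, lowest-energy
conformer). Candidates are first screened cheaply by an ε_HOMO threshold
of −0.140 Hartree (inclusive); only survivors enter the second, more
expensive property round and the MLR prediction — the two-round economy
is enforced structurally in the pipeline.

The package provides, as separately usable modules:

* **structures** — SMILES parsing with carbanion-pattern detection (with a
  rejects report; nothing is silently dropped), seeded deterministic
  ETKDG conformer embedding with UFF ranking, energy-window and
  RMSD pruning, multi-frame XYZ and SDF I/O;
* **qm interface** — an engine-agnostic backend contract (optimize /
  single-point / thermochemistry / Hirshfeld capabilities) with
  content-addressed result caching, parsers for engine output dialects,
  a directory-of-outputs backend, and a deterministic non-physical mock
  for plumbing tests;
* **descriptors** — Sterimol L/B1/B5 and buried Sterimol implemented from
  scratch (coarse angular grid + golden-section refinement, with a dense
  brute-force reference scan as an independent oracle), Boltzmann
  weighting, ensemble aggregation, descriptor-table assembly;
* **modeling** — OLS on z-scored features with raw-space coefficients,
  train/test evaluation, leave-one-out and k-fold cross-validation,
  exhaustive best-subset search with a persisted leaderboard, the HOMO
  filter, and the Mayr-nucleophilicity benchmark correlation;
* **pipeline + CLI** — the end-to-end screening workflow with
  per-molecule failure sandboxing, reproducible seeding, cached reruns,
  CSV/JSON reports and ggplot2 figures;
* **fixtures** — synthetic generators (toy geometries with frozen oracle
  values, planted linear descriptor tables, fake engine outputs) so the
  whole artifact builds and tests without any quantum-chemistry engine.

## Worked example

Screen a small set of carbanions with the deterministic mock backend and
a model trained on a synthetic descriptor table:

```r
library(co2screen)

smi <- tempfile(fileext = ".smi")
example_smiles_file(smi)             # 8 carbanions + 3 invalid lines

tab <- simulate_descriptor_table(seed = 1)
names(tab)[1:3] <- c("homo_boltz", "site_dipole_boltz", "buried_b1_boltz")
model <- fit_mlr(tab, names(tab)[1:3])

cfg <- pipeline_config(smi, backend = mock_backend(), model = model,
                       n_confs = 10, seed = 1)
report <- run_screening(cfg)
print(report)
#> <screening_report: 11 input, 8 pattern-valid, 5 passed filter, 5 predicted stable, 3 rejected>
report$predictions[, c("id", "epsilon_homo", "stability_call")]
#>                         id epsilon_homo stability_call
#> 1                 indenide       -0.139         stable
#> 2                 cp_anion       -0.131         stable
#> 3               fluorenide       -0.143   screened-out
#> 4      malononitrile_anion       -0.128         stable
#> 5 phenylacetonitrile_anion       -0.139         stable
#> 6      phenylacetone_anion       -0.142   screened-out
#> 7        diphenylmethanide       -0.145   screened-out
#> 8               acac_anion       -0.137         stable
render_report(report, "runs/demo")   # tables, summary.json, two figures
```

The 11 input lines are conserved as 8 predictions + 3 rejects (a methide
with no carbon neighbor, a neutral molecule, a nitrogen-flanked anion,
each with its reason). Candidates with ε_HOMO ≥ −0.140 Hartree received
an affinity prediction; with the mock backend these numbers exercise the
plumbing, not chemistry.

The same run from a shell:

```sh
Rscript inst/cli/co2screen.R screen --input mols.smi --out runs/demo --seed 1
Rscript inst/cli/co2screen.R train  --table descriptors.csv --subset-size 3 --out runs/fit
```

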