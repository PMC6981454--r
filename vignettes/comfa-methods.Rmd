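---
title: "CoMFA 3D-QSAR for purine cytotoxicity data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoMFA 3D-QSAR for purine cytotoxicity data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`comfa` models the cytotoxicity of a library of 31 2,6,9-trisubstituted
purine derivatives (series I: 4a–k, series II: 4l–u, series III: 7a–j)
screened against a panel of seven human tumour cell lines plus MRC-5
non-neoplastic fibroblasts. The scientific question is a classic 3D-QSAR
one: which steric and electrostatic features of the molecules, expressed as
interaction fields around their aligned 3D structures, explain the
variation in potency (pIC50), and where around the scaffold is bulk or
charge favourable or detrimental?

The method is comparative molecular field analysis (CoMFA): sample the
interaction energy of a probe atom on a 3D lattice around the aligned
molecules, regress pIC50 on the thousands of grid energies with partial
least squares (PLS), validate internally by leave-one-out (LOO)
cross-validation and externally on a held-out test set, and read the model
back as contour maps of coefficient × column-spread values.

# Pipeline and model

## Activities

IC50 values are stored in micromolar. Censored entries (">25", ">100" —
the compound was inactive up to the highest soluble concentration) keep
the bound with a `censored` flag; they are **never** converted to pIC50 and
never enter a design matrix. For modelling, pIC50 = −log10(IC50 · 10⁻⁶).
With the packaged data this leaves 20 modelled compounds for HL-60 and 14
for NCI-H460, which reproduces the published training/test percentages
(15/5 = 75%/25% and 10/4 = 71%/29%).

The packaged activity table is a *reconstruction*: the full published
matrix is not available as machine-readable data, so every value printed in
the text (including the MRC-5 values implied by the published selectivity
indices SI(7h) = 250 and SI(7f) = 77 on HL-60) is used verbatim and the
remaining cells are filled in consistently with all qualitative activity
statements. See `inst/extdata/README.txt`. Conclusions drawn from the
packaged models therefore test the *machinery* faithfully but the exact
statistics depend on reconstructed cells.

## Structures

SMILES for all 42 compounds (31 final + 11 intermediates) were transcribed
manually from the systematic names. The guard against transcription error
is the test that recomputes each molecular formula from the SMILES and
compares it with the stored HRMS-derived formula (42/42 agree).

One 3D conformer per compound is built by seeded ETKDG distance-geometry
embedding followed by MMFF94 minimization (RDKit, called through the system
Python). This replaces the original protocol of force-field optimization
plus simulated-annealing conformer selection in a proprietary modelling
suite; we chose determinism and reproducibility over fidelity to an engine
we cannot run. With a fixed seed the construction is bit-deterministic: the
same (SMILES, seed) gives identical coordinates on every run and in every
process, which the suite asserts. (Open Babel's 3D builder was evaluated
for this role and rejected: its rotor search is time-seeded and not
reproducible across processes.)

Partial charges are Gasteiger charges (iterative partial equalization of
orbital electronegativity) as implemented in Open Babel. The classic CoMFA
protocol used Gasteiger–Hückel charges; the Hückel π-correction is omitted
here, a documented deviation. Charges conserve the net formal charge and
respect topological symmetry (asserted on benzene).

Alignment is rigid-body least squares (Kabsch) of each molecule's purine
core atoms onto those of the first molecule. The nine-atom bicyclic
9H-purine core is the default template, a choice the original rigid
alignment left unstated; it is exposed as the `scaffold` argument so users
can redefine it. Substructure matching runs VF2 on the element-labelled
heavy-atom graph (igraph); among multiple matches the mapping minimizing
the scaffold RMSD is kept. All 31 purines align below 0.5 Å core RMSD.

## Fields

The lattice is axis-aligned with 2.0 Å spacing and 4.0 Å margin, anchored
at floor(min − margin) per axis so layouts reproduce across runs; nodes are
linearized x-fastest, 0-based. The probe is the standard CoMFA sp³ carbon:
vdW radius 1.52 Å, charge +1.0 e, well depth 0.107 kcal/mol.

The original publication never prints its energy functionals (they are
modelling-suite internals), so the package uses the widely documented CoMFA
defaults:

* steric: Lennard-Jones 6-12, E = ε[(R/r)¹² − 2(R/r)⁶] with
  R = r_atom + r_probe and ε the geometric mean of atom and probe well
  depths (per-element well depths from Tripos-style tables), truncated at
  +30.0 kcal/mol;
* electrostatic: Coulomb with k = 332.0637 kcal·Å·mol⁻¹·e⁻² and
  distance-dependent dielectric ε(r) = r (hence E ∝ 1/r²), clamped to
  ±30.0 kcal/mol. At sterically excluded nodes (steric energy at the
  cutoff) the electrostatic value is replaced by the column mean over
  non-clashing molecules — the standard CoMFA convention, switchable via
  `exclude_electrostatic`.

Hydrogens are included in field evaluation (charges are all-atom). Columns
with energy standard deviation below 2.0 kcal/mol are dropped before PLS
(the published column filter value).

## PLS, validation, statistics

PLS is NIPALS on column-centered data (no scaling — fields share energy
units), deterministic, with the regression vector recovered as
b = W(PᵀW)⁻¹q. At full rank its predictions equal ordinary least squares
(asserted to 1e-8); for univariate X one component reduces to simple
regression (asserted to 1e-10).

LOO q² = 1 − Σ(yᵢ − ŷ₍₋ᵢ₎)² / Σ(yᵢ − ȳ)². The original equation does not
say whether ȳ is the full-sample or per-fold mean; the package defaults to
the full-sample mean (the common SAMPLS/LOO convention) with a
`q2_mean = "fold"` option. SAMPLS itself is treated as a mere acceleration
of LOO and not implemented separately. The component count N is chosen to
maximize LOO q² over 1..floor(n/3) — the "fewer components than 33.3% of
the compounds" quality rule applied as a hard cap; ties go to the smaller N.

Final statistics: r² = 1 − RSS/TSS; SEE = √(RSS/(n − N − 1)) (the
convention of the original modelling suite; no formula is printed);
external r²pred = (SD − PRESS)/SD with SD the squared deviations of test
activities from the training mean and PRESS the squared test errors. Field
contributions are block sums of |coefficient| × column standard deviation,
normalized to 1.

The published random split membership is unrecorded, so the packaged
reproduction uses seed 20191225 (the publication date) and reports the
resulting membership. Exact published statistics (q² 0.791/0.745, r²
0.969/0.959, SEE 0.127/0.142, r²pred 0.968/0.976) are therefore **not**
bit-reproducible: they depended on a proprietary force field, charge
scheme, alignment and an unrecorded split. What the package asserts
instead are the structural properties: finite q², r², SEE, r²pred with
q² ≤ r², N ≤ floor(n/3), and steric dominance over electrostatics (the
published direction of the 70/30 contribution split).

## Contour maps

Display values are STDEV×COEFF (PLS coefficient times column standard
deviation), the default display of the original figures. The publication
does not state its contour levels; the package defaults to the 80th/20th
percentiles of each block's value distribution, config-exposed. "Polyhedra"
are reported as connected components of selected nodes under 6-neighbour
connectivity, each annotated with its centroid, size and distances to the
C-2, C-6 and N-9 substituent centroids of a reference compound (7h by
default). The qualitative published claims — a steric-disfavoured region
flanking the C-2 substituent in the HL-60 model — are checked in the run
report (`contour_checks`).

# Synthetic data

The generator exists so the field → PLS → contour chain can be tested
end-to-end against known ground truth:

* `generate_planted_matrix()` draws X = TPᵀ + E with a chosen number of
  latent factors and y = Xb + noise; by default the planted b lies in the
  latent span of X, so its direction is identifiable and recovery
  (cosine > 0.95 at noise 0.01) is a sharp test. Defaults (n = 20
  molecules, 2 latent factors) mirror the size of a typical CoMFA training
  set so that LOO behaviour is comparable.
* `generate_toy_library()` enumerates purine-scaffold molecules with a
  variable-bulk substituent at C-2 and a para-substituted 6-aryl group,
  planting pIC50 = base + w_s·(heavy atoms at C-2) + w_e·(EWG at para) +
  noise, and emits the same CSV formats the real pipeline reads.

What the generator does *not* emulate: heteroscedastic biological assay
noise, censoring mechanisms, conformational flexibility, or nonlinear
structure–activity relationships. Passing synthetic tests demonstrates the
implementation is correct for the model class PLS assumes; it does not
validate CoMFA as a model of real cytotoxicity.

# Numerical choices and degenerate inputs

* Energies are exactly truncated (steric ≤ 30, |electrostatic| ≤ 30); a
  probe at an atom centre yields exactly +30.
* A constant response gives the zero PLS model with intercept ȳ; LOO on a
  constant response errors (q² undefined).
* Requesting more components than the X/y covariance supports errors.
* `split_train_test()` guarantees at least one compound per set; sizes are
  round(fraction·n).
* Contour extraction on all-equal values warns and returns empty sets.
* Exact masses use IUPAC/CODATA monoisotopic masses with the proton mass
  1.007276 u; the electron mass is neglected, matching printed HRMS
  "Calcd" values at 4 decimals. Three printed values (compounds 4t, 4q,
  7f) are inconsistent with their own printed molecular formulas (e.g. 4q
  prints the value of the C25 homologue) and are excluded from the
  golden-value test; the other 27 agree within 0.0002 m/z.

# Problem sizes

The packaged reproduction models 20 (HL-60) and 14 (NCI-H460) compounds on
grids of roughly 1,500–2,500 nodes per field; the synthetic studies use
20–30 molecules with 60–200 descriptor columns and 20 replicate seeds for
the noise-degradation study. These sizes keep a full test run in well under
a minute of numerical work while leaving every statistical property
testable.

# Known limitations

* Single-conformer, rigid-alignment treatment; no conformational ensembles.
* Gasteiger rather than Gasteiger–Hückel charges.
* The reconstructed activity table pins only the published cells exactly.
* No CoMSIA fields, region focusing, bootstrap or y-scrambling validation.
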