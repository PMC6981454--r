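# comfa — CoMFA 3D-QSAR for purine cytotoxicity data

`comfa` is an R implementation of comparative molecular field analysis
(CoMFA), built around a packaged library of 31 2,6,9-trisubstituted purine
derivatives screened for cytotoxicity against seven human tumour cell lines
and MRC-5 control fibroblasts. It is aimed at medicinal/computational
chemists who want a fully scripted, reproducible 3D-QSAR pipeline: every
stage — structures, charges, alignment, fields, PLS, validation, contour
maps — is an ordinary R function with tests.

## The method

For molecules aligned on a common scaffold, CoMFA samples two interaction
fields on a cubic lattice (2 Å spacing) around the set, using an sp³ carbon
probe (vdW radius 1.52 Å, charge +1 e):

* **steric**: Lennard-Jones 6-12, E = ε[(R/r)¹² − 2(R/r)⁶],
  R = r_atom + r_probe, truncated at +30 kcal/mol;
* **electrostatic**: Coulomb with distance-dependent dielectric ε(r) = r,
  E = 332.0637 · q·q_probe / r², clamped to ±30 kcal/mol.

After dropping columns with energy spread < 2 kcal/mol, activity
(pIC50 = −log₁₀ IC50 [M]) is regressed on the fields by NIPALS partial
least squares. Internal validity is leave-one-out

q² = 1 − Σ(yᵢ − ŷ₍₋ᵢ₎)² / Σ(yᵢ − ȳ)²,

with the component count N chosen to maximize q² under the cap
N ≤ ⌊n/3⌋. External validity on a held-out test set is

r²_pred = (SD − PRESS) / SD,

with SD the squared deviations of the test activities from the training
mean and PRESS the squared test errors. The model is read back as
STDEV×COEFF contour maps: grid regions where bulk (green/yellow) or charge
(blue/red) favours or hurts potency.

## Worked example

```r
library(comfa)

# rule-of-five profile and exact mass of the lead compound (7h)
lib <- load_library()
lipinski_profile(lib$smiles[lib$id == "7h"])
#> MW 427.9  logP 4.48  HBD 0  HBA 9  [M+H]+ 428.1596  violations 0

# full reproduction run on the HL-60 leukaemia cell line
run <- run_pipeline(comfa_config(cell_line = "HL-60"))
print(run)
#> CoMFA run: HL-60, 20 compounds (train 15 / test 5)
#> q2 = 0.659  r2 = 0.956  SEE = 0.133  N = 3
#> r2pred = 0.182  (PRESS = 0.902, SD = 1.102)
#> field contributions: steric 99.3%, electrostatic 0.7%

run$contour_checks$steric_disfavoured_near_C2
#> [1] TRUE
```

Reading the output: 20 of the 31 purines have a measurable (non-censored)
HL-60 IC50 and are modelled, split 15/5 into training and test. The model
explains the training activities well (r² = 0.956, SEE = 0.133 pIC50
units) with honest internal predictivity (LOO q² = 0.659) from N = 3
latent components; steric field variation dominates the explanation, and a
steric-disfavoured contour region flanks the C-2 substituent — i.e. bulky
C-2 groups cost potency, matching the observed SAR. `run$predictions`
holds per-compound observed/fitted/LOO values and `run$regions` the
located contour regions.

The packaged activity table is a documented partial reconstruction (all
individually published IC50/SI values verbatim, unpublished cells filled
consistently with the published qualitative statements — see
`inst/extdata/README.txt`), so model statistics characterize this
reconstruction, not the original unpublished data matrix.

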