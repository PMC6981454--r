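Packaged data
=============

compounds.csv
  id,smiles,series,formula,name for the 31 final 2,6,9-trisubstituted purine
  derivatives (series I: 4a-k, II: 4l-u, III: 7a-j) and the 11 synthetic
  intermediates (2a-e, 3a-e, 6a; series = "intermediate", excluded from QSAR
  modelling). SMILES were transcribed manually from the systematic names;
  every record is validated in the test suite by recomputing the molecular
  formula from the SMILES and comparing it with the stored HRMS-derived
  formula.

activities_reconstructed.csv
  compound_id,cell_line,ic50_um,censored  (IC50 in micromolar; censored=TRUE
  means "greater than ic50_um").  PARTLY SYNTHETIC RECONSTRUCTION: the full
  published cytotoxicity table is not available as machine-readable data.
  All individually published values are used verbatim (e.g. 7c/7g/7h on
  NCI-H460 = 4.8/2.2/1.3 uM; 7g/7h on HL-60 = 0.30/0.40 uM; 4r on CACO2 =
  27 uM; MRC-5 values fixed by the published selectivity indices SI(7h,
  HL-60)=250 and SI(7f,HL-60)=77). The remaining cells are filled with
  values consistent with every qualitative statement of the activity and
  SAR discussion (activity thresholds, orderings between analogues,
  censoring rules, and the modelled-compound counts of 14 for NCI-H460 and
  20 for HL-60 implied by the published 71%/75% training-set percentages).
  Ambiguous cells are exactly those not pinned by a printed number.
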