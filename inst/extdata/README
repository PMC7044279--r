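aml_cohort_covariate_counts.tsv

Counts of molecular abnormalities, karyotypic lesions, FAB class and sex in
the low-expresser (n = 160) and high-expresser (n = 72) subgroups of a
published 232-patient adult AML microarray cohort, as printed in the study
that reported them. Each row gives the number of carriers of one covariate
level per subgroup; the one-vs-rest 2x2 table for a level is
  [[count_low, 160 - count_low], [count_high, 72 - count_high]].
Used as a desk-reproducible input for the exact Fisher test
(fisherExact2x2) and by scripts/acceptance.R.
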