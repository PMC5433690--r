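# Reference fixture

Counts transcribed from the clinical-features summary table of the
original 125-patient ocular adnexal LPD cohort (54 RFH, 28 ALH, 43
MALToma) and from its IgH clonality analysis (73 evaluable samples after
52 quality-control failures; clonal rearrangements in 0/35 RFH, 8/17 ALH,
18/21 MALToma).

Only counts and printed summary statistics are stored; percentages are
always recomputed from the counts. Per-subject data were not published in
machine-readable form, so no per-patient fixture exists: per-patient
tables are produced by the synthetic generator (`generate_cohort()`),
which is calibrated to these marginals.

Note: the source table prints 70.07% for periorbital swelling in RFH,
but the printed count is 40 of 54 = 74.07%; this package recomputes the
percentage from the count.
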