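n_phenopackets	n_cohorts	n_diseases	n_unique_alleles	n_publications	n_present	n_excluded	n_features	n_features_with_onset
6668	423	475	3834	959	53693	61598	115291	4913
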