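statistic	printed
lm_concordance_pct	93.1
overall_concordance_pct	93.8
primary_liver_concordance_pct	100
ci_lower	0.87
ci_upper	0.97
well_differentiated_pct	96.2
poorly_differentiated_pct	88.7
biopsy_pct	88.9
resection_pct	95.5
scc_subgroup_pct	70
p_differentiation	0.47
p_specimen_type	0.31
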