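characteristic	level	n
specimen_type	Biopsy	36
specimen_type	Resection	110
differentiation	Well	26
differentiation	Poorly	71
differentiation	Undefined	49
histology	Adenocarcinoma	114
histology	Neuroendocrine	16
histology	Squamous cell carcinoma	10
histology	Melanoma	4
histology	Sarcoma	2
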