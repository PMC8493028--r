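tumor_type	n_samples	n_correct	printed_sensitivity
Ovary	23	23	100
Colorectum	23	22	95.7
Breast	19	19	100
Neuroendocrine	16	15	93.8
Pancreas	16	14	87.5
Gastroesophagus	10	7	70.0
Melanoma	4	4	100
Cervix	4	4	100
Lung	3	2	66.7
Adrenal	3	3	100
Germ cell	2	2	100
Head&neck	2	1	50.0
Sarcoma	2	2	100
Kidney	2	2	100
Urinary	1	1	100
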