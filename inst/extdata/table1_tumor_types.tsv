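tumor_type	n
Liver	16
Colorectum	23
Ovary	23
Breast	19
Neuroendocrine	16
Pancreas	16
Gastroesophagus	10
Melanoma	4
Cervix	4
Lung	3
Adrenal	3
Germ cell	2
Head&neck	2
Sarcoma	2
Kidney	2
Urinary	1
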