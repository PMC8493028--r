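id	gender	age	sample_type	reference_diagnosis	predicted	histological_subtype	differentiation
43	Male	69	Surgery	Gastroesophagus	Urinary	AC	Poorly
54	Male	61	Surgery	Colorectum	Gastroesophagus	AC	Well
57	Male	70	Biopsy	Pancreas	Colorectum	AC	Poorly
59	Male	74	Biopsy	Gastroesophagus	Liver	AC	Poorly
70	Male	53	Biopsy	Pancreas	Liver	AC	Poorly
75	Male	63	Biopsy	Lung	Head&neck	SCC	Poorly
114	Male	59	Surgery	Gastroesophagus	Liver	SCC	Poorly
119	Female	68	Surgery	Neuroendocrine	Endometrium	NET	Poorly
134	Female	63	Surgery	Head&neck	Liver	SCC	Poorly
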