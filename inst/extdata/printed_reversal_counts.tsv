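organ	direction	n_deg	n_reversed	pct_printed	organ_total
brain	up	424	203	48	1939
brain	down	1515	357	24	1939
liver	up	1670	1086	65	3488
liver	down	1818	459	25	3488
heart	up	723	462	64	1236
heart	down	513	388	76	1236
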