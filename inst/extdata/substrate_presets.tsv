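name	dp_min	dp_max	cri_min	cri_max	n_microfibrils	min_total
avicel	250	300	0.5	0.6	5	1000000
filter_paper	700	800	0.4	0.5	4	1000000
bacterial_cellulose	1800	2000	0.85	0.95	2	1000000
cotton	2500	3000	0.85	0.95	2	1000000
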