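name	enzyme_class	activity_iu_per_mg	notes
EGI	EG_nonproc_CBM	0.4	T. reesei endoglucanase I
EGII	EG_nonproc_CBM	0.4	assumed equal in activity to EG I
CBHI	CBH1_proc	0.8	T. reesei cellobiohydrolase I (Cel7A), reducing-end attack
CBHII	CBH2_proc	1.6	T. reesei cellobiohydrolase II (Cel6A), non-reducing-end attack
BG	BG	NA	beta-glucosidase, dosed in IU per g glucan
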