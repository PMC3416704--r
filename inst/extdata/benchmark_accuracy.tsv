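reference_set	scheme	avg_accuracy	random_accuracy	reported_gain_pct
Far-Western blotting	idbos	0.409	0.144	184
Far-Western blotting	hypergeometric	0.313	0.144	118
Far-Western blotting	occurrence	0.178	0.144	24
Isothermal titration calorimetry	idbos	0.542	0.172	215
Isothermal titration calorimetry	hypergeometric	0.469	0.172	173
Isothermal titration calorimetry	occurrence	0.286	0.172	66
Nuclear magnetic resonance	idbos	0.632	0.246	157
Nuclear magnetic resonance	hypergeometric	0.534	0.246	117
Nuclear magnetic resonance	occurrence	0.331	0.246	34
Surface plasmon resonance	idbos	0.567	0.218	160
Surface plasmon resonance	hypergeometric	0.496	0.218	128
Surface plasmon resonance	occurrence	0.320	0.218	47
PDB complex PPIs	idbos	0.842	0.235	258
PDB complex PPIs	hypergeometric	0.746	0.235	217
PDB complex PPIs	occurrence	0.566	0.235	141
Mouse homologous PPIs	idbos	0.318	0.099	222
Mouse homologous PPIs	hypergeometric	0.293	0.099	198
Mouse homologous PPIs	occurrence	0.207	0.099	110
Domain-domain interactions	idbos	0.225	0.152	48
Domain-domain interactions	hypergeometric	0.215	0.152	42
Domain-domain interactions	occurrence	0.174	0.152	15
Co-pathway	idbos	0.350	0.199	76
Co-pathway	hypergeometric	0.315	0.199	59
Co-pathway	occurrence	0.235	0.199	18
Co-disease	idbos	0.306	0.160	91
Co-disease	hypergeometric	0.298	0.160	86
Co-disease	occurrence	0.214	0.160	34
Co-function	idbos	0.122	0.082	48
Co-function	hypergeometric	0.123	0.082	50
Co-function	occurrence	0.095	0.082	16
Co-expression	idbos	0.036	0.031	15
Co-expression	hypergeometric	0.035	0.031	14
Co-expression	occurrence	0.033	0.031	6
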