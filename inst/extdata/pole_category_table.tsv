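pole_substitution	pold1_substitution	n_nonsyn_snv	msi_status	tissue
p.A189D, p.F367V	p.R244H	16632	MSS	uterus
p.K717N	p.E318G	6155	MSS	uterus
p.P286R	-	3686	MSS	uterine body
p.L120I, p.P286R	-	1846	MSS	uterus
p.V411L	-	1212	MSS	uterus
p.P286R	p.A706T	9782	MSS	colon (transverse)
p.P286R	p.D402N	7593	MSS	colon (ascending)
p.P286R	-	3491	MSS	colon (rectum)
p.P286R	-	2903	MSS	colon (rectum)
p.P286R	-	2699	MSS	colon (rectum)
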