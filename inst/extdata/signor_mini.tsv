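ENTITYA	TYPEA	ENTITYB	TYPEB	EFFECT	MECHANISM
TP53	protein	MDM2	protein	up-regulates quantity by expression	transcriptional regulation
MDM2	protein	TP53	protein	down-regulates quantity by destabilization	ubiquitination
AKT1	protein	GSK3B	protein	down-regulates activity	phosphorylation
SIGNOR-C1	complex	CCND1	protein	up-regulates	transcriptional regulation
FBLN5	protein	ITGB1	protein	unknown	binding
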