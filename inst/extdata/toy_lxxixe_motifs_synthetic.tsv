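protein_id	peptide	class	phosphosites	source
SYN_L01	LSPIIEEDS	LxxIxE	2	validated
SYN_L02	LATIYEDTQ	LxxIxE	8	validated
SYN_L03	LSSIVESGN	LxxIxE		validated
SYN_L04	LTPIHESEK	LxxIxE		validated
SYN_L05	LQTIWETDA	LxxIxE		predicted
SYN_L06	LSCIFESNG	LxxIxE		predicted
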