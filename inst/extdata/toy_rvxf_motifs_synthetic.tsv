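protein_id	peptide	class	phosphosites	source
SYN_R01	KKRVSFAE	RVxF	5	validated
SYN_R02	EGRVSFID	RVxF	5	validated
SYN_R03	QPKVTFGE	RVxF		validated
SYN_R04	ALRVNFDQ	RVxF		validated
SYN_R05	GNKVAFPE	RVxF		validated
SYN_R06	RMRVGFNL	RVxF		validated
SYN_R07	PAKVQFAD	RVxF		validated
SYN_R08	DTRVTFEK	RVxF		predicted
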