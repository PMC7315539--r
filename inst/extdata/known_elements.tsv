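name	sequence	description
EE_core	AATATC	evening element core
EE_full	AAATATCT	full evening element (EE)
CBS	AAAAATCT	CCA1-binding site
ME	CCACAC	morning element
TBX	AAACCCT	telo-box
SBX	AAGCCC	starch synthesis box
SORLIP1	GCCAC	light-induction SORLIP1 motif
UP1ATMSD	GGCCCA	protein-synthesis UP1ATMSD motif
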