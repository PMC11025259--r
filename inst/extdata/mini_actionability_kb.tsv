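# Frozen mini actionability knowledge base (breast cancer).
# variant_filter: comma-separated protein changes; empty = any non-silent variant.
gene	alteration_type	variant_filter	oncokb_loe	escat
ERBB2	amplification		1	I
PIK3CA	mutation	E542K,E545K,E545A,E545G,H1047R,H1047L,H1047Y,C420R,Q546E,Q546R	1	I
BRCA1	mutation		1	I
BRCA1	deletion		1	I
BRCA2	mutation		1	I
BRCA2	deletion		1	I
PTEN	deletion		4	II
AKT1	mutation	E17K	3	II
ESR1	mutation	D538G,Y537S,Y537N,Y537C,E380Q	3	II
ERBB2	mutation	L755S,V777L,S310F	3	II
MDM4	amplification		4	none
FGFR1	amplification		3	none
FGFR2	amplification		3	none
CCND1	amplification		4	none
EGFR	amplification		4	none
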