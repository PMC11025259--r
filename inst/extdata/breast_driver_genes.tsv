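# Curated list of established breast-cancer driver genes used for driver
# tagging. This is a package-curated stand-in list, not a verbatim copy of
# any published catalog.
gene
TP53
PIK3CA
MYC
CCND1
PTEN
ERBB2
ZNF703
GATA3
RB1
MAP3K1
MAP2K4
AKT1
AKT2
AKT3
CDH1
ARID1A
ARID1B
ARID2
KMT2C
KMT2D
NCOR1
TBX3
RUNX1
CBFB
PIK3R1
FOXA1
SF3B1
CTCF
NF1
ATM
CHEK2
BRCA1
BRCA2
PALB2
ESR1
ERBB3
EGFR
FGFR1
FGFR2
MDM4
CDKN1B
CDKN2A
SMAD4
STK11
KRAS
HRAS
NRAS
BAP1
CASP8
MAP2K7
NOTCH1
NOTCH2
PTPN22
PTPRD
SETD2
SPEN
TET2
USP9X
ZFP36L1
GPS2
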