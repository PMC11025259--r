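# hg19 coordinates of commonly assessed breast-cancer genes (approximate gene spans)
gene	chrom	start	end
TP53	chr17	7571720	7590868
ERBB2	chr17	37844393	37884915
BRCA1	chr17	41196312	41277500
MAP2K4	chr17	11924204	12047147
NF1	chr17	29421945	29704695
PIK3CA	chr3	178866311	178952497
PTEN	chr10	89623195	89728532
GATA3	chr10	8096667	8117164
FGFR2	chr10	123237848	123357972
BRCA2	chr13	32889617	32973809
RB1	chr13	48877887	49056122
AKT1	chr14	105235686	105262088
ESR1	chr6	152011631	152424408
MYC	chr8	128748315	128753680
FGFR1	chr8	38268656	38326352
ZNF703	chr8	37553329	37557466
IL7	chr8	79587978	79717758
HEY1	chr8	80676245	80680098
CCND1	chr11	69455873	69469242
ATM	chr11	108093211	108239829
EGFR	chr7	55086725	55324313
CDH1	chr16	68771128	68869444
ARID1A	chr1	27022894	27108601
MDM4	chr1	204485511	204542871
KMT2C	chr7	151832010	152133090
AKT3	chr1	243663021	244006886
CDKN1A	chr6	36644237	36655116
STK11	chr19	1205798	1228431
BAP1	chr3	52435020	52444366
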