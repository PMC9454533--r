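gene	chrom	start	end
ABCB1	1	1000000	1049999
AKT1	2	1000000	1049999
AKT2	3	1000000	1049999
AKT3	4	1000000	1049999
APC	5	1000000	1049999
ARID1A	6	1000000	1049999
ARID1B	7	1000000	1049999
ATM	8	1000000	1049999
ATR	9	1000000	1049999
AURKA	10	1000000	1049999
BAP1	11	1000000	1049999
BARD1	12	1000000	1049999
BRCA1	13	1000000	1049999
BRCA2	14	1000000	1049999
BRIP1	15	1000000	1049999
CASP8	16	1000000	1049999
CCND1	17	1000000	1049999
CDH1	18	1000000	1049999
CDK4	19	1000000	1049999
CDK6	20	1000000	1049999
CDKN1B	21	1000000	1049999
CDKN2A	22	1000000	1049999
CHEK1	1	1200000	1249999
CHEK2	2	1200000	1249999
CREBBP	3	1200000	1249999
EGFR	4	1200000	1249999
EP300	5	1200000	1249999
ERBB2	6	1200000	1249999
ERBB3	7	1200000	1249999
ERBB4	8	1200000	1249999
ESR1	9	1200000	1249999
ESR2	10	1200000	1249999
FANCA	11	1200000	1249999
FANCD2	12	1200000	1249999
FGFR1	13	1200000	1249999
FGFR2	14	1200000	1249999
FGFR3	15	1200000	1249999
FOXA1	16	1200000	1249999
GATA3	17	1200000	1249999
HRAS	18	1200000	1249999
IGF1R	19	1200000	1249999
JAK2	20	1200000	1249999
KDM6A	21	1200000	1249999
KIT	22	1200000	1249999
KMT2C	1	1400000	1449999
KMT2D	2	1400000	1449999
KRAS	3	1400000	1449999
MAP2K4	4	1400000	1449999
MAP3K1	5	1400000	1449999
MDM2	6	1400000	1449999
MET	7	1400000	1449999
MLH1	8	1400000	1449999
MSH2	9	1400000	1449999
MSH6	10	1400000	1449999
MTOR	11	1400000	1449999
MUC16	12	1400000	1449999
MYC	13	1400000	1449999
NBN	14	1400000	1449999
NCOR1	15	1400000	1449999
NF1	16	1400000	1449999
NOTCH1	17	1400000	1449999
NOTCH2	18	1400000	1449999
NRAS	19	1400000	1449999
PALB2	20	1400000	1449999
PBRM1	21	1400000	1449999
PDGFRA	22	1400000	1449999
PGR	1	1600000	1649999
PIK3CA	2	1600000	1649999
PIK3R1	3	1600000	1649999
PMS2	4	1600000	1649999
PTEN	5	1600000	1649999
PTPN11	6	1600000	1649999
RAD50	7	1600000	1649999
RAD51	8	1600000	1649999
RAD51C	9	1600000	1649999
RAD51D	10	1600000	1649999
RB1	11	1600000	1649999
RET	12	1600000	1649999
RUNX1	13	1600000	1649999
SETD2	14	1600000	1649999
SF3B1	15	1600000	1649999
SMAD4	16	1600000	1649999
SMARCA4	17	1600000	1649999
SPEN	18	1600000	1649999
STK11	19	1600000	1649999
SYNE1	20	1600000	1649999
TBX3	21	1600000	1649999
TP53	22	1600000	1649999
TSC1	1	1800000	1849999
TSC2	2	1800000	1849999
VHL	3	1800000	1849999
XRCC2	4	1800000	1849999
ZNF217	5	1800000	1849999
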