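MUC7
MUC5B
ZNF91
TP53
TTN
SPOP
KMT2D
FOXA1
AR
PTEN
RB1
BRCA2
ATM
CDK12
PIK3CA
CTNNB1
APC
KRAS
NRAS
BRAF
EGFR
ERBB2
ALK
MYC
MYCN
NOTCH1
NOTCH2
FAT1
FAT2
FAT3
FAT4
CNTN6
ZNF43
ZNF808
ZNF347
ZNF729
ZNF721
ZNF429
ZNF626
ZNF292
CPEB2
SELENOP
EP400
NPW
FLG
DPP10
ALMS1
KRTAP13-3
SYNE1
SYNE2
MUC16
MUC4
MUC6
MUC2
MUC5AC
OBSCN
CSMD1
CSMD2
CSMD3
LRP1B
LRP2
RYR1
RYR2
RYR3
PCLO
DNAH5
DNAH9
DNAH11
USH2A
HMCN1
FBXW7
ARID1A
ARID1B
ARID2
SMARCA4
PBRM1
SETD2
KDM6A
KMT2A
KMT2C
CREBBP
EP300
NCOR1
NCOR2
SPEN
CHD1
CHD4
ATRX
DAXX
IDH1
IDH2
CUL3
ACACA
SCN5A
SCN10A
FAM71B
GRIN2A
GRIN2B
ERG
ETV1
ETV4
TMPRSS2
NKX3-1
HOXB13
AKT1
MTOR
TSC1
TSC2
STK11
NF1
NF2
SUFU
PTCH1
GLI1
SMO
WNT5A
WNT7A
LRP5
LRP6
AXIN1
AXIN2
TCF7L2
GSK3B
DVL1
CCND1
CCNE1
CDK4
CDK6
CDKN1B
CDKN2A
CDKN2B
E2F1
E2F3
MDM2
MDM4
ATR
CHEK1
CHEK2
BRCA1
PALB2
RAD51
FANCA
FANCD2
MSH2
MSH6
MLH1
PMS2
POLE
POLD1
ERCC2
ERCC5
XPC
NBN
MRE11
BARD1
BRIP1
RAD54L
TET2
DNMT3A
ASXL1
EZH2
SRSF2
SF3B1
U2AF1
ZRSR2
STAG2
SMC1A
SMC3
RAD21
CTCF
KLF5
GATA2
GATA3
RUNX1
ETS2
SPI1
IRF4
NFKB1
RELA
TRAF3
CYLD
TNFAIP3
CARD11
MYD88
JAK1
JAK2
STAT3
STAT5B
SOCS1
IL7R
FLT3
KIT
PDGFRA
MET
ROS1
RET
NTRK1
NTRK3
FGFR1
FGFR2
FGFR3
IGF1R
INSR
IRS2
PTPN11
SHP2
SOS1
RASA1
RAF1
MAP2K1
MAP2K4
MAPK1
DUSP4
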