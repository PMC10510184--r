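# Synthetic driver-gene list for examples and tests (not a published census)
TP53
AR
PTEN
RB1
SPOP
FOXA1
BRCA2
ATM
CDK12
PIK3CA
KRAS
BRAF
MYC
APC
CTNNB1
NOTCH1
FBXW7
ARID1A
CHD1
KMT2D
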