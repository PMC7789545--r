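BRCA1
BRCA2
EGFR
TP53
ATM
PALB2
CHEK2
PTEN
KRAS
PIK3CA
CDH1
RAD51C
RAD51D
BARD1
MLH1
MSH2
BRIP1
ERBB2
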