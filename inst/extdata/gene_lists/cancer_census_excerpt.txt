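# Cancer gene census excerpt (example list for prioritization tiers;
# substitute the full licensed census for production use)
APC
ARID1A
ARID1B
ATM
BRAF
BRCA1
BRCA2
CDKN2A
EGFR
ERBB2
FBXW7
FGFR1
FGFR2
FGFR3
IDH1
IDH2
KRAS
NRAS
HRAS
NF1
NF2
NOTCH1
PIK3CA
PTEN
RB1
SETD2
STAG2
BCOR
AKT1
ALK
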