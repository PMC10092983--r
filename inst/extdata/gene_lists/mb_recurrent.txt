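# Genes recurrently altered in medulloblastoma (curated example list;
# substitute your own literature-derived list for production use)
CTNNB1
DDX3X
SMO
PTCH1
SUFU
GLI2
TP53
KMT2D
KMT2C
KDM6A
SMARCA4
MYC
MYCN
TERT
CREBBP
EP300
CSNK2B
PRDM6
GFI1
GFI1B
ZMYM3
KBTBD4
ELP1
U1-snRNA
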