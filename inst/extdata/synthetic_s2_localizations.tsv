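gene	subcell	hpa	busca
ACACA	Cytosol	Cytosol	mitochondrion
ACO2	Mitochondria	Mitochondria	mitochondrion
MDH1	Cytosol	Cytosol	cytoplasm
MDH2	Mitochondria	Mitochondria	mitochondrion
GOT1	Cytosol	Cytosol	cytoplasm
GOT2	Mitochondria	Mitochondria	mitochondrion
ACAT1	Mitochondria	Uncertain	mitochondrion
ACAT2	Cytosol	Cytosol	cytoplasm
HK2	Cytosol	Uncertain	cytoplasm
GLUL	Unknown	Cytosol	cytoplasm
GLS2	Unknown	Unknown	mitochondrion
NIT2	Mitochondria	Cytosol	nuclear
LDHD	Mitochondria	Mitochondria	secreted
PC	Mitochondria	Mitochondria	mitochondrion
HAGHL	Unknown	Cytosol	secreted
TKFC	Uncertain	Uncertain	cytoplasm
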