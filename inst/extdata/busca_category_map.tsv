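raw_label	category
mitochondrion	mitochondria
cytoplasm	cytoplasm
nucleus	nucleus
extracellular	secretory
extracellular space	secretory
plasma membrane	secretory
membrane	secretory
endomembrane system	secretory
organelle membrane	secretory
lysosome	secretory
endoplasmic reticulum	secretory
golgi apparatus	secretory
chloroplast	unknown
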