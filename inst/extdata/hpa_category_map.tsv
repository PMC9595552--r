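raw_label	category
Nucleoplasm	nucleus
Nuclear bodies	nucleus
Nuclear speckles	nucleus
Nuclear membrane	nucleus
Nucleoli	nucleus
Nucleoli fibrillar center	nucleus
Nucleoli rim	nucleus
Kinetochore	nucleus
Mitotic chromosome	nucleus
Mitochondria	mitochondria
Cytosol	cytoplasm
Cytoplasmic bodies	cytoplasm
Aggresome	cytoplasm
Rods & Rings	cytoplasm
Microtubules	cytoplasm
Microtubule ends	cytoplasm
Mitotic spindle	cytoplasm
Centrosome	cytoplasm
Centriolar satellite	cytoplasm
Cytokinetic bridge	cytoplasm
Midbody	cytoplasm
Midbody ring	cytoplasm
Cleavage furrow	cytoplasm
Actin filaments	cytoplasm
Focal adhesion sites	cytoplasm
Intermediate filaments	cytoplasm
Endoplasmic reticulum	secretory
Golgi apparatus	secretory
Vesicles	secretory
Endosomes	secretory
Lysosomes	secretory
Peroxisomes	secretory
Lipid droplets	secretory
Plasma membrane	secretory
Cell Junctions	secretory
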