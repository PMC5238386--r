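name,formula
serine,C3H7NO3
GABA,C4H9NO2
2-aminoadipic acid,C6H11NO4
saccharopine,C11H20N2O6
lysine,C6H14N2O2
glutamate,C5H9NO4
pipecolic acid,C6H11NO2
Pro-Phe,C14H18N2O3
Phe-Gln,C14H19N3O4
Pro-Trp,C16H19N3O3
6-amino-2-oxohexanoate,C6H11NO3
2-aminoadipate-6-semialdehyde,C6H11NO3
alanine,C3H7NO2
threonine,C4H9NO3
tyrosine,C9H11NO3
tryptophan,C11H12N2O2
histidine,C6H9N3O2
methionine,C5H11NO2S
phenylalanine,C9H11NO2
leucine,C6H13NO2
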