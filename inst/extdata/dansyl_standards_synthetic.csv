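name,formula,tag_count,rt_s
serine,C3H7NO3,1,185
GABA,C4H9NO2,1,412
2-aminoadipic acid,C6H11NO4,1,341
saccharopine,C11H20N2O6,2,298
lysine,C6H14N2O2,2,520
glutamate,C5H9NO4,1,230
pipecolic acid,C6H11NO2,1,455
Pro-Phe,C14H18N2O3,1,705
Phe-Gln,C14H19N3O4,1,668
Pro-Trp,C16H19N3O3,1,742
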