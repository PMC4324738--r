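disease	genes
Leber hereditary optic neuropathy	MT-ND1,MT-ND4,MT-ND4L,MT-ND6,MT-CO1,MT-CO3,MT-CYB,MT-ND2,MT-ND5
Leigh syndrome	MT-ATP6,MT-ND1,MT-ND2,MT-ND3,MT-ND4,MT-ND5,MT-ND6,MT-TK,MT-TV,MT-TW
MELAS syndrome	MT-TL1,MT-ND1,MT-ND5
Alzheimer disease	MT-RNR2
Diabetes mellitus and deafness	MT-TL1
Diabetes and myopathy	MT-ND6
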