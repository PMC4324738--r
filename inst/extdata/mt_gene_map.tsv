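# Human mitochondrial gene intervals used by the annotation examples.
# MT-RNR2, MT-ATP6, MT-CO3: published coordinates; MT-TL1: MITOMAP
# reference coordinates. 1-based inclusive; MT-ATP6 and MT-CO3 share
# boundary position 9207.
name	start	end	strand	description
MT-RNR2	1671	3229	H	16S ribosomal RNA
MT-TL1	3230	3304	H	tRNA leucine 1 (UUA/G)
MT-ATP6	8527	9207	H	ATP synthase F0 subunit 6
MT-CO3	9207	9990	H	cytochrome c oxidase subunit III
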