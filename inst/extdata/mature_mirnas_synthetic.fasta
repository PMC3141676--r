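>syn-miR-101 MIMAT_SYN0001 Synthetica exemplaris miR (synthetic stand-in)
CGCAGCTAAGGACCGTTAGTA
>syn-miR-102 MIMAT_SYN0002 Synthetica exemplaris miR (synthetic stand-in)
GTTGTTTAAGAAACATTCCGGG
>syn-miR-103 MIMAT_SYN0003 Synthetica exemplaris miR (synthetic stand-in)
TAGTTGCAAGTTATGTGGGT
>syn-miR-104 MIMAT_SYN0004 Synthetica exemplaris miR (synthetic stand-in)
TTACATTTATTAGTACGGAGA
>syn-miR-105 MIMAT_SYN0005 Synthetica exemplaris miR (synthetic stand-in)
CAGTAAAATGCTAAAAAATAGC
>syn-miR-106 MIMAT_SYN0006 Synthetica exemplaris miR (synthetic stand-in)
TTCTCCACTCCGACAAGGTCGCTA
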