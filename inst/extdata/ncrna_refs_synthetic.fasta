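>rRNA_SSU_syn1|rRNA|genbank
GTCGGTCGTTCCGGACGAAAGGGGTAGGAACACATTTATAAAGCATTATGTAATAGGCACCGGGTGCCCTAGGTATGGCTCTGACCCAAGACAGATATTCACGTACAGGTAGCCAGGGCGTTAATCGGCGCGCCATGTCTGGCTTAAGCAACTGCTCCGAGCGTCTCCCGTACCTGGCGTTGCACAAGGGCCTACGTCCACTGCCTAAGGTCATCAATTGCCGTCTTCGTTGGCAATCTTACAACATAAATCTGCTAGTTTTTCAGGATCTCGGCTCCATTACCCCGCATATTCTGACGTCCGTGACCTGGCCAGAGTAC
>rRNA_LSU_syn1|rRNA|rfam
TGTATTCTGATTTGTTAAAGTATCACCTGCCAGGCGGGAAGTGCGTCGGGTTATCACTATCTCAGCCTCTGGTAGGAAATGTTACCCGGCATTAGAGCACGTTGTTACCATGAGTCGGAGTCACGGTGGCACAACACGAACGTAGCGCGGAGCCGCCTGGGTACGGTGTATAAGCACACGACTGTCGGGCCTTCCTACGGTTTAACGAGCATCCTGGGGCGCCACTGAGGTTACTCTCAGTACTATGGCTCTGTGGGTGTTAGTTTGGATTTTCGGCAACAATGGTGCGAACGACTGGATCCCGATCCCAGCTTCTGCTGGCACTGCTGCACACTTCTCGATTAGAGGATACGTGATTCTACCTTAAGTGGCGCTGAGGAGGGTGTTCTGGTCCCCCTGAAGTTAACACATATCGCGGAT
>tRNA_Ala_syn1|tRNA|genbank
GTTTCGGTTATTTAACCATGGTAGCCATGCCTTGAACACGGGCCTGGCTCACCCCTCGCGCGTATCTATTACCATC
>tRNA_Gly_syn1|tRNA|rfam
ATGCAGCGCTGCATAGTTCCTAACTGGATCCAACATGTTAAGCCGTGTAGCATAATAGAAGATAGCTCCGACGT
>snRNA_U1_syn1|snRNA|rfam
CAAACACATGGTCAGCCCTATTAACTTCTGTCTCGGTCGTTTTTAAACTAAAAGCCAGTAGTGGGGCATTCCGCCTCGGCAGCGGCTTATATCTGCTCCTTTAGGCGTGCGTGATTAAACTGGGGAGTCGTTTGAGGCGTAGCGTCACGG
>snRNA_U2_syn1|snRNA|genbank
ATCAGTTGGTGCTCTTCGTGCTCGCAACGTCCAATAGAATCGACCCCGTCATCGATTGTACCGTGTTAGAGCAGCAAAAGTCACGCCCAACTCAAAGCGGTCAATATGTATTACGACACA
>snoRNA_syn1|snoRNA|rfam
GGACAGCGCTAGATGTCCACGAAGACTTAGTTGTTCCCCCCGGGAGCCCGGTGCTCTTCGAGGGTGCGCACACTGCCCCGCGGCATATTGGGATA
>snoRNA_syn2|snoRNA|genbank
GCCCGGACGGGACTTGTTTGGGGAAAGAGGTGCCCGTCTTAACGTGTATCTCTGTCACTGACACTCAAGTCTCGCGTTGCGTTAGACT
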