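>t1 toy transcript, cds 10-40
CCCCCCCCCCATGGCTGCAGGAGAAGGCGCTGGAGCATAATTTTTTTTTTTTTTTTTTTT
>t2 toy transcript, cds 0-21
ATGAAACCCGGGTTTGACTGAACGTACGTACGTACGTACGTACGT
>t3 toy transcript, cds 30-66
GGGGGAAAAACCCCCTTTTTGGGGGAAAAAATGCATCACCAACAGAACAAAGACGAAGCTTGCTGAACGTAC
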