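>synthetic_ACTB_construct synthetic two-exon test construct
CGGATGTACATATGTGTAGTAAACTAAGCAAAACCGCAACACAGTATGCAATGTGGGCTA
CAGGTCATCACCATTGGCAATCTCCGCCTACATGAGGTAGCCAAAACCGACACGCGGCCA
CAGGACTCCATACCCAAGAAAGATGGCCCCACAGAAGCACTGCCACACTGAGAATAGGCC
GCTATGGATATCCGTAAGGATCTGTATGCAACTTTCTGAATTTCGTTGGTTCAGGTGCGC
AGGAAAGCTCATTAACATAGGACTTCAGT
>synthetic_HPRT1_construct synthetic two-exon test construct
TCGCTTGCGTAAAAGGATCATGACTGCTAACCAATGGCTGCCAGGCGTGTTGATACACAA
TGGTCAAAAGAACTCCTCGAAGTTCAATGGCAACAATCCAACAAAGTCTGGCCGATATCC
CACCCTAAATCGTCCTTGGATACGCCCTCGATTACATCCTGTGCCCGAATACAGTGAAAC
GGATTTTCGGATCGTGAGTTCTGTCAGAAGAGCCCT
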