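gene,forward,reverse,probe,forward_exon,reverse_exon,amplicon_mrna,amplicon_dna
ACTB,CAGGTCATCACCATTGGCAAT,GCATACAGATCCTTACGGATATCCA,CACAGGACTCCATACCCAAGAAAGATGGC,3,4,149,455
B2M,AAGGAGCCGCAGGTCTAC,CTTGCTCTTTGCCGTCATAC,CCGGGATGAGCACGGTCTGAAGAATT,2,4,151,1138
HMBS,GGTTGAGATGCTCCGTGAGTTT,GGCTCTTCTCCCCAATCTTAGAA,CCTGACCTCTGCTTTGAGATTGTTGCCA,3,4,153,798
HPRT1,TGGTCAAAAGAACTCCTCGAAGT,TGTAATCGAGGGCGTATCCAA,TCCAACAAAGTCTGGCCGATATCCCA,6,7,96,972
PGK1,GTTTATGTCAATGATGCTTTTGGAA,GCCTTTGCAAAATAATCCAGTTCT,CATCGTGCTCACAGCTCCATGGTAGGT,4,5,82,431
PLA2,GCACAAGACATTTGGCAGTTGT,TGTGACATTTGTGGCTTTCCTTA,CAACACATTGTGGTGGAACACCAGTACTCA,2,3,138,5846
PPIA,CCCGTCGTGTTCTTCGACAT,CCCTTGTAGCCAAATCCCTTCT,CACCTTCGAGCTCTTCGCTGACAAGG,1,2,140,NA
RPL13,TCGTGCTGGCAGAGGATTC,TCGTCCGAGCAAACCTTTTG,TAATGCCCGCCAGTTTAAGCTCTTCTAGGC,3,4,71,908
RPLP0,TTGGGCATCACCACAAAGATT,CCCACTTTGTCTCCGGTCTTAA,CATCACTCAGAATTTCAATGGTCCCTCGGG,4,5,82,431
TBP,CTTCGTGCCCGAAATGCT,GCGCAGTAGTACGTGGTTCTCTT,CTCATAATAACAGCAGCAAAACGCTTGGGA,4,5,82,1689
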