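gene,full_name,ena_genbank,refseq,ensembl
ACTB,Beta actin,L08165,NM_205518,ENSGALT00000015673
B2M,Beta-2-microglobulin,M84767,NM_001001750,ENSGALT00000040255
HMBS,Hydroxymethylbilane synthase,BX932073,XM_417846,ENSGALT00000000380
HPRT1,Hypoxanthine phosphoribosyl transferase 1,AJ132697,NM_204848,ENSGALT00000009843
PGK1,Phosphoglycerate kinase 1,L37101,NM_204985,ENSGALT00000012893
PLA2,Phospholipase A2 group IV A,U10329,NM_205423,ENSGALT00000008121
PPIA,Peptidylprolyl isomerase A (Cyclophilin A),GQ849480,NM_001166326,ENSGALT00000044106
RPL13,Ribosomal protein L13,D26318,NM_204999,ENSGALT00000009974
RPLP0,Ribosomal phosphoprotein P0,L28704,NM_204987,ENSGALT00000011731
TBP,TATA box binding protein,D83127,NM_205103,ENSGALT00000037720
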