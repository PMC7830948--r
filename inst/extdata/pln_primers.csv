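gene,forward,reverse,accession
p53,CTAGCTCCCATCACTTCATCCC,AAATGCAGACAGGCTTTGCAG,NM_001127233.1
caspase3,GAGCTTGGAACGGTACGCTA,CCGTACCAGAGCGAGATGAC,NM_001284409.1
GAPDH,AGAGAGGCCCAGCTACTCG,GGCACTGCACAAGAAGATGC,NM_008084.3
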