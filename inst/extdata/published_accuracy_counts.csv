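subgroup,a,b,c,d
her2_tn,22,21,0,39
luminal,0,27,0,11
anthracycline_taxane,16,14,0,27
taxane,6,5,0,7
anthracycline,0,2,0,5
anti_her2_nac,12,5,0,14
no_anti_her2_nac,4,13,0,9
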