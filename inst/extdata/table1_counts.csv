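row_type,locus,level,spaid_pos,spaid_neg,fever_pos,fever_neg,arthritis_pos,arthritis_neg,vesicular_pos,vesicular_neg,otitis_pos,otitis_neg,amyloidosis_pos,amyloidosis_neg
genotype,CNV_14.3,2,128,15,93,30,62,28,35,36,31,43,28,13
genotype,CNV_14.3,4,24,17,20,19,17,15,9,19,2,25,2,4
genotype,CNV_14.3,6,3,2,1,2,0,3,0,3,1,3,1,0
genotype,CNV_16.1,2,3,3,1,3,0,4,0,4,1,4,1,0
genotype,CNV_16.1,6,25,16,21,18,17,15,9,19,2,25,3,4
genotype,CNV_16.1,10,127,15,92,30,62,27,35,35,31,42,27,13
allele,CNV_14.3,1,280,47,206,79,141,71,79,91,64,111,58,30
allele,CNV_14.3,3,30,21,22,23,17,21,9,25,4,31,4,4
allele,CNV_16.1,1,31,22,23,24,17,23,9,27,4,33,5,4
allele,CNV_16.1,5,279,46,205,78,141,69,79,89,64,109,57,30
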