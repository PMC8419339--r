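case,gene,dna_vaf,rna_vaf,fpkm,detected
ALL1,SETD2,29.45,33.33,40.51,TRUE
ALL3,PAX5,38.34,29.81,238.84,TRUE
ALL4,NOTCH3,50.33,-,0.4,FALSE
ALL4,TET2,53.55,34.48,10.6,TRUE
ALL4,PAX5,6.37,13.64,78.66,TRUE
AML1,NOTCH3,52.36,-,1.04,TRUE
AML2,NOTCH3,4.62,-,0.79,FALSE
AML2,RUNX1,43.35,52.94,105.24,TRUE
AML2,RUNX1,45.35,44.20,105.24,TRUE
AML3,NF1,65.3,68.57,27.73,TRUE
MPAL2,TET2,53.33,63.64,14.54,TRUE
MPAL2,NF1,45.9,61.54,6.1,TRUE
MPAL4,SH2B3,47.95,42.86,39.96,TRUE
MPAL4,NOTCH3,48.29,66.67,1.09,TRUE
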