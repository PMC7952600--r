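name,sequence,is_isotype_control
CD3,TATCAATT,FALSE
CD11b,TATTACCA,FALSE
CD15,TTTGCTCC,FALSE
CD33,AGGCGAAC,FALSE
CD34,ACATATTC,FALSE
CD38,CTAAACTC,FALSE
CD45,TCCATAGT,FALSE
CD56,TTAACTTA,FALSE
CD71,AACATCCA,FALSE
IgG1,GGAGCTGC,TRUE
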