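biomarker,direction
STAT3,up
CEBPB,up
ERK1/2,up
NF-kB,up
FOXO1,down
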