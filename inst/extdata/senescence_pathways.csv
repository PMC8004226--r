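pathway_code,gene
CC,HDAC4
CC,HDAC5
OSIS,JUN
DDR,RAD51
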