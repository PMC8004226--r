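compound_id,target_symbol,interaction
ZINC2558154,TOP1,modulator
ZINC2558154,CA1,modulator
ZINC2558154,CES1,modulator
ZINC2558154,ACHE,modulator
ZINC2558154,PTPN6,modulator
ZINC2558154,RAD51,modulator
ZINC34383300,CCR1,inhibitor
ZINC34383300,CCR2,inhibitor
ZINC34383300,CCR3,inhibitor
ZINC34383300,CCR6,inhibitor
ZINC34383300,CCR7,inhibitor
ZINC34383300,CCR8,inhibitor
ZINC34383300,CCR9,inhibitor
ZINC34383300,CXCL10,inhibitor
ZINC34383300,FOS,inhibitor
ZINC34383300,JUN,inhibitor
ZINC95911093,HDAC1,inhibitor
ZINC95911093,HDAC2,inhibitor
ZINC95911093,HDAC4,inhibitor
ZINC95911093,HDAC5,inhibitor
ZINC95911093,HDAC6,inhibitor
ZINC95911093,HDAC8,inhibitor
ZINC95911093,TYR,inhibitor
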