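name	partition	min_p
dayhoff	AGPST,C,DENQ,FWY,HKR,ILMV	NA
minmax9	D,PV,AIMSY,GFT,L,NH,W,RCQK,E	0.112
minmax6	GFTW,AHILMSY,NPV,E,D,RCQK	0.21
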