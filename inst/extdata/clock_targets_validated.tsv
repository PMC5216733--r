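mirna	gene
hsa-let-7e-5p	PER1
hsa-let-7e-5p	CLOCK
hsa-miR-125b-5p	PER1
hsa-miR-125b-5p	RORA
hsa-miR-125b-5p	TIPIN
hsa-miR-140-3p	NPAS2
hsa-miR-140-3p	TIMELESS
hsa-miR-99b-5p	PER1
hsa-miR-99b-5p	RORA
hsa-miR-99b-5p	TIMELESS
hsa-miR-19b-3p	TIMELESS
hsa-miR-19b-3p	NR1D2
hsa-miR-139-5p	TIMELESS
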