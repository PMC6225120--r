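taxon	primer	sequence	size
A_dahurica	ADA-F	ATCGGCGTCTTTCCAAAATGC	183
	ADA-R	GCACAACTTCTCAGGTGTGCCT	
A_anomala	AAN-F	AAAATCATTCAGGCGCGGAGAG	259
	AAN-R	AAACCGGCACAACTTCTCATGT	
A_japonica	AJA-F	GGCCACTCCTGGGTGGCCAGAG	309
	AJA-R	CGGGAGGCCAGTTTCCGCCAGA	
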