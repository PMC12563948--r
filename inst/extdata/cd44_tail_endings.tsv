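abbreviation	accessions	ending
CD44SP	P16070-2;AAB27917.1	GVGRRKS
CD44sol	NP_001001392.1;P16070-19;AAC70782.1	SLHCSQQSKKVWAEEKASDQQWQWSCGGQKCGGQKAKWTQRRGQQVSGNGAFGEQGVVRNSRPVYDS
CD44 V7-19 alternative end	NP_001427280.1;NP_001427281.1	GDCGSMAWVKKYFSFIFL
CD44 exon 1-V3 alternative end	NP_001427282.1	IICLFTRRIYKQHTVTKSLGFQVQRDTTDCMDGQNGAFGYPRWRAGVFKAVLPTAAASLTVLSGRSHVLNPKVFYDRMQRTLRCLPIWLN
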