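name	replaced_start	replaced_end	insert	source_note
exons 2-19 spliced out	23	742	GVGRRKS	CD44SP / P16070-2
exons 3-19 spliced out (SST tail)	78	742	SST	AAH52287.1 and related
exons 3-19 spliced out (soluble tail)	78	742	SLHCSQQSKKVWAEEKASDQQWQWSCGGQKCGGQKAKWTQRRGQQVSGNGAFGEQGVVRNSRPVYDS	CD44sol / P16070-19; deposited length 139 inconsistent with descriptor arithmetic (144)
part of exon 5 spliced out	192	223	A	microexon variant; no primary literature reference
exon V2 spliced out	223	266	S	P16070-4 and related
exons V2-V3 spliced out	223	308	I	NP_001427264.1 and related
exons V2-V4 spliced out	223	385	I	NP_001427270.1 and related
exons V2-V7 spliced out	223	472	N	CD44E / P16070-10
exons V2-V9 spliced out	223	536	N	CD44v10 / P16070-11
exons V2-V10 spliced out	223	604	R	CD44s / P16070-12
exons V2-15 spliced out	223	625	R	CD44s-exon15 / P16070-18
part of exon V3 spliced out	266	273		microexon variant; deposited as 8-residue deletion; no primary literature reference
exons V4-V7 spliced out	308	472	N	NP_001427275.1 and related
exon V6 spliced out	385	428	T	P16070-6; no primary literature reference
exons V7-19 spliced out	428	742	GDCGSMAWVKKYFSFIFL	NP_001427280.1 and related
exon V9 spliced out	506	535	R	P16070-7; no primary literature reference
exons V9-V10 spliced out	506	604	R	P16070-14 and related
exon V10 spliced out	536	604	R	P16070-8; no primary literature reference
exon 19 spliced out (short tail)	675	742	S	CD44st / P16070-15
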