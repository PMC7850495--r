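# msiskew marker panel: panel23
# chrom	start	end	marker_id	repeat_unit	ref_length
chr1	120053013	120053053	BAT40	T	40
chr1	159032486	159032496	AIM2-A10	A	10
chr10	114925269	114925278	TCF7L2-A9	A	9
chr11	63142521	63142532	SLC22A9-T11	T	11
chr11	104879681	104879691	CASP5-T10	T	10
chr13	31722620	31722637	HSPH1-T17	T	17
chr14	23652346	23652367	NR-21	A	21
chr17	48278905	48278913	XYLT2-G8	G	8
chr17	56435160	56435167	RNF43-G7	G	7
chr18	57027751	57027760	LMAN1-A9	A	9
chr19	49458971	49458979	BAX-G8	G	8
chr2	39564893	39564920	MONO-27	A	27
chr2	47641559	47641585	BAT26	A	26
chr2	48030639	48030647	MSH6-C8	C	8
chr2	51288379	51288423	D2S123	CA	44
chr2	95849361	95849384	NR-24	T	23
chr2	148683685	148683693	ACVR2A-A8	A	8
chr3	30691871	30691881	TGFBR2-A10	A	10
chr3	130733046	130733057	ASTE1-A11	A	11
chr4	55598211	55598236	BAT25	T	25
chr5	79970915	79970923	MSH3-A8	A	8
chr6	108214770	108214780	SEC63-A10	A	10
chr7	55238868	55238881	EGFR-A13	A	13
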