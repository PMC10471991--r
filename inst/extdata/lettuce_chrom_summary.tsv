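chrom	length_bp	n_snps
1	214780997	9995
2	217124359	9560
3	256900232	7295
4	377162472	13920
5	339292695	11255
6	192650122	5291
7	195410018	6797
8	309580090	10614
9	203529833	6804
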