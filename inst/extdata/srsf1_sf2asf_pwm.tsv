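# motif_id=SRSF1_SF2ASF threshold=1.956 provenance=ESEfinder 3.0 SF2/ASF (SRSF1) additive score matrix, published values (Cartegni et al. 2003, Nucleic Acids Res 31:3568-3571)
pos	A	C	G	T
1	-1.14	1.37	-0.21	-1.58
2	0.62	-1.10	0.17	-0.50
3	-1.58	0.73	0.48	-1.58
4	1.32	0.33	-1.58	-1.13
5	-1.58	0.94	0.33	-1.58
6	-1.58	-1.58	0.99	-1.13
7	0.62	-1.58	-0.11	0.27
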