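strain	allele	chrom	start	end	printed_size_bp	map_units	map_err
KR4968	h2717	I	753745	1072570	318826	-13.23	2.0
KR4978	h2727	I	1742835	1745216	2382	-12.63	1.5
KR4984	h2733	I	1833730	1833737	8	-11.62	2.7
KR5009	h2758	I	2100906	2105867	4962	-12.10	2.1
KR4969	h2718	I	2897024	2897046	21	-6.09	2.0
KR5037	h2787	I	5112626	5127686	15059	-2.06	1.6
KR5006	h2755	I	6175541	6180417	4877	NA	NA
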