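batch	dose_uM	n_f1	n_lethal	printed_frequency_pct
1	750	437	24	5.5
1	750	550	25	4.5
1	750	436	24	5.5
2	375	145	3	2.1
2	750	580	13	2.2
2	1400	145	1	0.7
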