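allele	detection	size_bp	junction
h2727	Pindel	2	TTCTTTTCATTTCTCtaTGTTTGCCTATCACT
h2758	Pindel	4	TAATTTCACTGGAAtcatTGTCTTCCTTATCAC
h2718	Pindel	4	ATCCAATTTTCCGCcgcgCAGTCGCCAAAAAGG
h2755	Pindel	5	TAAATGACTACTgtaacGCTTGTGTCGATTTA
h2718	Pindel	5	TTCTAGGCATATattgcGAAATATCTTTATAA
h2718	Pindel	5	CTTGCGTGGGACCAgtcgtGTGGTCGAAACAGAC
h2718	Pindel	5	CAAATTGGAATGCTGccgaaCTCTTGCCCATGTCT
h2733	Pindel	6	TTTGGAGCTGTCGAcacgttCCGCGCCGCACTATA
h2733	Pindel	7	CATAAATCGCAAActgcgttCTTCAGCAACAATAT
h2733	IGV	8	ATTTTCTGGTGAGTGacgcgataAAATCAATATTTTCT
h2787	Pindel	8	ATATTCGTGAAGAcattgttcCAACGCTGCACAATT
h2718	Pindel	9	GTGACCTTAAGAAgaacgagatGAGATGGAGAGTTGA
h2787	Pindel	10	TCCAACACAGAGAtgccgtagcgTGCAAATTAGGCTTT
h2718	Pindel	13	ACTGCATCTGgaattccgatatcGATTTCACGATCGAA
h2727	Pindel	22	AAAaccacgcaggcgacgcctacatACCACGCAGGCAGCC
h2718	IGV	21	GACtcctcagcttcagcagaatacTCCTCAGCTTCAGCAGAATATCCATG
h2727	Pindel	58	CTTTTATACGTAACCtttcc<48>ataaaTGAAAAATTGCTTCC
h2733	Pindel	77	GACGACGACGAGGAAccccc<67>aaagcACCACGTGGAGATTA
h2744	Pindel	104	TGTTTCAAAATATACatctg<94>ctaatATAAATATCCATGCC
h2717	Pindel	165	AGtgccaacaacaatgtattc<137>caacaatcaTGCCAACAACAATGC
h2717	Pindel	331	GAGGAAAAGGATAACacatt<321>aaaaaTCGCAAAAAACGCAT
h2727	Pindel	394	TGGTTCGGCCAATGAatttt<384>ctcagTGTTTACGGTTTATA
h2733	Pindel	1003	ATAGAGAATATACGGtatgc<993>gcaatTATCAGATTTCTTGT
h2727	IGV	2382	ACATTCCTTTTCCGGggccg<2372>tcattTTTACGCCTGTCAG
h2755	IGV	4877	CCTCATTTTGTGTGTtaatt<4867>ttaatTCACTATAATCCAAA
h2758	IGV	4962	AATATCTTCAAGCCGtcttc<4952>atcacCATTAAATTATTAGT
h2755	Pindel	13671	ATCCCACTTTGTAGAagaac<13661>ggagtTCCAAAGAGTCATGC
h2787	IGV	15059	GACAATTCGAGAGAAagaat<15049>ttgtgTTTGCGGAGTCGCAT
h2717	IGV	318826	CGTGAGTCGTTCCGAttggc<318816>ttcgtAGATAAAACTATTA
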