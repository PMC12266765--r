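toyB	5	32	g1	0	+	protein
toyB	50	90	g2	0	-	rRNA
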