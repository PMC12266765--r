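toyA	10	40	g1	0	+	protein
toyA	60	100	g2	0	-	rRNA
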