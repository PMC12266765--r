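chrM	0	68	TrnF	0	+	tRNA
chrM	69	1024	Rnr1	0	+	rRNA
chrM	1024	1093	TrnV	0	+	tRNA
chrM	1093	2675	Rnr2	0	+	rRNA
chrM	2675	2750	TrnL1	0	+	tRNA
chrM	2750	3707	ND1	0	+	protein
chrM	3707	3776	TrnI	0	+	tRNA
chrM	3776	3845	TrnQ	0	-	tRNA
chrM	3845	3913	TrnM	0	+	tRNA
chrM	3913	4951	ND2	0	+	protein
chrM	4951	5019	TrnW	0	+	tRNA
chrM	5020	5089	TrnA	0	-	tRNA
chrM	5091	5164	TrnN	0	-	tRNA
chrM	5196	5263	TrnC	0	-	tRNA
chrM	5263	5330	TrnY	0	-	tRNA
chrM	5330	6875	COX1	0	+	protein
chrM	6872	6941	TrnS1	0	-	tRNA
chrM	6944	7014	TrnD	0	+	tRNA
chrM	7015	7699	COX2	0	+	protein
chrM	7700	7765	TrnK	0	+	tRNA
chrM	7766	7970	ATP8	0	+	protein
chrM	7926	8607	ATP6	0	+	protein
chrM	8606	9390	COX3	0	+	protein
chrM	9390	9458	TrnG	0	+	tRNA
chrM	9458	9806	ND3	0	+	protein
chrM	9807	9875	TrnR	0	+	tRNA
chrM	9876	10173	ND4L	0	+	protein
chrM	10166	11544	ND4	0	+	protein
chrM	11545	11614	TrnH	0	+	tRNA
chrM	11614	11673	TrnS2	0	+	tRNA
chrM	11673	11744	TrnL2	0	+	tRNA
chrM	11741	13565	ND5	0	+	protein
chrM	13551	14070	ND6	0	-	protein
chrM	14070	14139	TrnE	0	-	tRNA
chrM	14144	15288	CYTB	0	+	protein
chrM	15288	15355	TrnT	0	+	tRNA
chrM	15355	15422	TrnP	0	-	tRNA
chrM	15422	16299	Dloop	0	+	dloop
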