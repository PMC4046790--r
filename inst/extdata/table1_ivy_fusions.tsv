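sample	tcga_id	gene5	gene3	junction_reads	wt5	wt3	band	strand5	strand3	chrom	pos5	pos3	type
SN214	TCGA-74-6583	MON2	MARS	47	6	3	12q14	+	+	chr12	62981936	57883990	In-frame fusion
SN214	TCGA-74-6583	MDM1	UAR	196	4	NA	12q15	-	-	chr12	68717849	68876024	Extended 3' UTR
SN214	TCGA-74-6583	SLC35E3	UAR	470	0	NA	12q15	+	-	chr12	69145972	68489752	Truncated gene
SN238	NA	YEATS4	SLC35E3	232	6	4	12q15	+	+	chr12	69753803	69152935	In-frame fusion
SN161	NA	PIK3C2B	DSTYK	95	3	0	1q32	-	-	chr1	204426856	205119924	In-frame fusion
SN195-1	NA	PLEKHA6	PIK3C2B	23	0	13	1q32	-	-	chr1	204320007	204439018	5' UTR
SN161	NA	CREB1	PARD3B	65	10	1	2q33	+	+	chr2	208442379	205829875	Out-of-frame fusion
SN214	TCGA-74-6583	SCFD2	CLOCK	10	4	6	4q12	-	-	chr4	53786892	56301763	In-frame fusion
SN159	NA	SEC61G	UAR	484	44	NA	7p11	+	-	chr7	51654097	54821716	No protein product
SN161	NA	LANCL2	RP11-745C15	274	8	0	7p11	+	+	chr7	55469013	54872359	Truncated gene
SN218	NA	ZNF713	UAR	51	2	NA	7p11	+	+	chr7	55991300	56082944	Truncated gene
SN154	TCGA-74-6573	ZNF713	UAR	14	10	NA	7p11	+	-	chr7	55980418	55945274	Truncated gene
SN187	TCGA-74-6578	FGFR3	TACC3	13	31	0	4p16	+	+	chr4	1808661	1737458	In-frame fusion
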