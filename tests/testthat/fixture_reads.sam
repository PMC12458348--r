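@HD	VN:1.6	SO:unsorted
@SQ	SN:t1	LN:60
@SQ	SN:t2	LN:45
@SQ	SN:t3	LN:72
r1	0	t1	5	255	28M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:1
r2	0	t1	11	255	30M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:2	NH:i:1
r3	0	t1	23	255	20M	*	0	0	AAAAAAAAAAAAAAAAAAAA	*	NM:i:3	NH:i:1
r4	0	t2	1	255	21M	*	0	0	AAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:2
r5	0	t2	3	255	25M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:1	NH:i:1
r6	0	t3	31	255	31M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:1
r7	0	t3	16	255	28M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:1
r8	0	t3	40	255	22M	*	0	0	AAAAAAAAAAAAAAAAAAAAAA	*	NM:i:1	NH:i:1
r9	16	t1	8	255	28M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:1
r10	16	t2	9	255	24M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAA	*	NM:i:0	NH:i:1
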