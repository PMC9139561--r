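hospital_id	a	b	c	d	e	f	g	h	i	j	total
Hospital 1	5	5	0	0	0	0	0	0	0	1	9
Hospital 2	5	5	0	0	1	0	0	1	0	1	7
Hospital 3	0	0	-	-	-	-	-	-	-	-	0
Hospital 4	5	5	0	0	0	0	0	0	0	1	9
Hospital 5	5	5	0	0	1	0	0	0	0	1	8
Hospital 6	5	5	0	0	1	0	0	0	0	1	8
Hospital 7	5	5	0	0	1	0	0	0	0	1	8
Hospital 8	5	5	0	0	0	0	0	0	0	1	9
Hospital 9	5	5	0	0	0	0	0	0	0	1	9
Hospital 10	5	5	1	1	1	0	0	0	0	1	6
Hospital 11	5	5	0	0	1	0	0	0	0	1	8
Hospital 12	5	5	0	0	1	0	0	0	0	1	8
Hospital 15	5	5	0	0	1	0	0	0	0	1	8
Hospital 16	5	5	0	0	0	0	0	0	0	0	10
Hospital 17	5	5	0	0	1	0	0	0	0	1	8
Hospital 18	5	5	1	0	0	0	0	0	0	1	8
Hospital 20	5	5	0	0	1	0	0	1	0	1	7
Hospital 21	5	5	0	0	0	0	0	0	0	1	9
Hospital 22	5	5	0	0	0	0	0	0	0	1	9
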