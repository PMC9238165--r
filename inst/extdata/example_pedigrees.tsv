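family_id	individual_id	father_id	mother_id	sex	status	age	proband	apoe	sorl1
SIM001	gpA1	.	.	male	0	81.4405296929181	0	.	.
SIM001	gpA2	.	.	female	.	.	0	.	.
SIM001	gpB1	.	.	male	0	52.9395297821611	0	.	.
SIM001	gpB2	.	.	female	0	70.5128554627299	0	33	1
SIM001	p1	gpA1	gpA2	male	0	71.8504426255822	0	42	0
SIM001	p2	gpA1	gpA2	unknown	0	47.2414777427912	0	.	.
SIM001	m1	gpB1	gpB2	female	0	51.5699032787234	0	.	.
SIM001	m2	gpB1	gpB2	unknown	0	46.9405043777078	0	33	1
SIM001	m3	gpB1	gpB2	unknown	1	62.7428708960479	0	23	1
SIM001	m4	gpB1	gpB2	unknown	0	66.4187322277576	0	.	.
SIM001	m5	gpB1	gpB2	unknown	1	66.2509405527636	0	33	1
SIM001	c1	p1	m1	unknown	1	61.0437069724806	1	43	1
SIM002	gpA1	.	.	male	0	63.6523161362857	0	.	.
SIM002	gpA2	.	.	female	0	49.3927939236164	0	.	.
SIM002	gpB1	.	.	male	0	79.5874092914164	0	.	.
SIM002	gpB2	.	.	female	.	.	0	.	.
SIM002	p1	gpA1	gpA2	male	0	54.7950870171189	0	.	.
SIM002	p2	gpA1	gpA2	unknown	.	.	0	.	.
SIM002	m1	gpB1	gpB2	female	0	46.6890526190400	0	.	.
SIM002	m2	gpB1	gpB2	unknown	0	74.0411537885666	0	.	.
SIM002	c1	p1	m1	unknown	0	73.5705703031272	0	.	.
SIM002	c2	p1	m1	unknown	1	68.2607225291709	1	34	1
SIM002	c3	p1	m1	unknown	0	56.0213880613446	0	33	1
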