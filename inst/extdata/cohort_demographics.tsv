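cohort	group	n	n_female	n_male	age_mean	age_sd
discovery	PD	96	42	54	69.9	7.52
discovery	NC	45	22	23	70.2	10.04
replication	PD	215	101	114	66.8	8.6
replication	NC	102	51	51	66.1	10.5
replication	ALS	59	26	33	61.9	10.5
paired_medication	PD	10	5	5	73.5	6.13
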