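gender	decade	age_mean	age_sd	weight_mean	weight_sd	height_mean	height_sd
men	20s	28	1	90	1	1.86	0.07
men	30s	35	3	90	11	1.85	0.04
men	40s	44	5	90	8	1.83	0.01
men	50s	53	3	83	19	1.81	0.10
men	60s	65	3	72	8	1.76	0.03
women	20s	25	4	64	1	1.71	0.06
women	30s	35	5	63	6	1.69	0.07
women	40s	44	3	62	1	1.65	0.06
women	50s	54	2	67	11	1.69	0.04
women	60s	62	2	69	18	1.65	0.03
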