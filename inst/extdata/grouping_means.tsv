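replicate	organ	grouping	mean_mfpkm	mean_fpkm	ratio
1	Leaves	High	232.23	75.65	3.07
1	Leaves	Moderate	146.87	29.17	5.03
1	Leaves	Low	76.96	7.66	10.05
1	Flowers	High	206.13	65.15	3.16
1	Flowers	Moderate	137.14	28.56	4.80
1	Flowers	Low	68.52	8.68	7.89
1	Roots	High	156.63	62.28	2.51
1	Roots	Moderate	111.23	28.44	3.91
1	Roots	Low	56.22	7.35	7.65
2	Leaves	High	221.14	88.55	2.50
2	Leaves	Moderate	176.68	17.94	9.84
2	Leaves	Low	99.06	3.75	26.42
2	Flowers	High	152.77	80.11	1.91
2	Flowers	Moderate	120.33	15.29	7.87
2	Flowers	Low	69.34	3.49	19.87
2	Roots	High	98.93	83.58	1.18
2	Roots	Moderate	65.81	11.74	5.61
2	Roots	Low	45.53	2.22	20.49
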