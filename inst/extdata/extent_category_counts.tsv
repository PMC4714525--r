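replicate	organ	high	low	equivalent	high_pct	low_pct	equivalent_pct
1	Leaves	13711	606	2094	83.5	3.7	12.8
1	Flowers	14807	762	2760	80.8	4.2	15.0
1	Roots	14275	413	2955	80.9	2.3	16.7
2	Leaves	16067	98	798	94.7	0.6	4.7
2	Flowers	18764	100	1443	92.4	0.5	7.1
2	Roots	17188	485	2337	85.9	2.4	11.7
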