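replicate	high_pct	low_pct	equivalent_pct
1	81.7	3.4	14.8
2	91.0	1.2	7.8
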