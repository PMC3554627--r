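trait1	trait2	trait3	trait4
1.00	0.45	0.45	0.45
0.45	1.00	0.45	0.45
0.45	0.45	1.00	0.45
0.45	0.45	0.45	1.00
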