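variant_id	trait1	trait2	trait3	trait4
rs101	0.222380	0.391267	0.883483	0.358968
rs102	0.025210	0.369946	0.301754	0.492169
rs103	0.207912	0.669024	0.493251	0.899400
rs104	0.216518	0.992118	0.501129	0.021810
rs105	0.444280	0.118521	0.402632	0.320252
rs106	0.134942	0.009463	0.977106	0.113816
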