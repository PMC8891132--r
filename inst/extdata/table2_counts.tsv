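group	II	I	III
2U	9	11	3
1U1D	5	11	1
2D	57	32	7
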