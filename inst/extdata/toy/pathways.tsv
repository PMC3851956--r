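P1	A	a
P1	A	b
P1	B	x
P1	B	y
P2	A	c
P2	A	d
P2	B	z
P2	B	w
P2	B	q
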