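# name toy_linear
# metabolite A_x x 2 external
# metabolite B c 2 balanced
# metabolite C_x x 2 external
# fixed vIn 10
vIn	A_x#ab	B#ab	irr	0	100
vOut	B#ab	C_x#ab	irr	0	100
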