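# name toy_diamond
# metabolite S_x x 2 external
# metabolite A c 2 balanced
# metabolite B c 2 balanced
# metabolite C c 2 balanced
# metabolite D c 2 balanced
# metabolite P_x x 2 external
# fixed vIn 10
vIn	S_x#ab	A#ab	irr	0	100
v1	A#ab	B#ab	irr	0	100
v2	A#ab	C#ba	irr	0	100
v3	B#ab	D#ab	irr	0	100
v4	C#ab	D#ab	irr	0	100
vOut	D#ab	P_x#ab	irr	0	100
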