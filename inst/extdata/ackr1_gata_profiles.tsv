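# ACKR1 base profiles at the four GATA-box-region diagnostic positions
# (5' to 3': c.-67, c.21+115, c.21+235, c.125). Archaic consensus bases may
# use IUPAC ambiguity codes (Y = C or T).
name	source	c.-67	c.21+115	c.21+235	c.125
NG_011626.3	H. sapiens reference	T	T	T	G
HAP897	H. sapiens ACB	C	C	T	A
HAP899	H. sapiens LWK	C	C	T	A
Chagyrskaya	H. neanderthalensis	T	C	T	A
Altai	H. neanderthalensis	T	C	T	A
Vindija	H. neanderthalensis	T	C	Y	A
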