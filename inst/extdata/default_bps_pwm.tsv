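A	C	G	T
0.28	0.26	0.22	0.24
0.26	0.24	0.22	0.28
0.10	0.42	0.08	0.40
0.04	0.06	0.05	0.85
0.45	0.06	0.38	0.11
0.85	0.05	0.04	0.06
0.08	0.40	0.07	0.45
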