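pos	A	C	G	T
m3	0.33	0.37	0.18	0.12
m2	0.60	0.13	0.14	0.13
m1	0.08	0.04	0.81	0.07
p1	0	0	1	0
p2	0	0	0	1
p3	0.53	0.03	0.42	0.02
p4	0.71	0.08	0.12	0.09
p5	0.06	0.05	0.82	0.07
p6	0.17	0.19	0.19	0.45
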