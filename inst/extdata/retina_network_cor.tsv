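gene	Neurod1	Pax6	Pcna	Sox2	Id2	Gap43	Pten	Zbed4
Neurod1	1	0.85	0.84	0.81	0.63	0.75	0.7	0.93
Pax6	0.85	1	0.88	0.95	0.73	0.68	0.63	0.84
Pcna	0.84	0.88	1	0.86	0.71	0.63	0.74	0.78
Sox2	0.81	0.95	0.86	1	0.76	0.68	0.65	0.8
Id2	0.63	0.73	0.71	0.76	1	0.64	0.67	0.54
Gap43	0.75	0.68	0.63	0.68	0.64	1	0.58	0.7
Pten	0.7	0.63	0.74	0.65	0.67	0.58	1	0.64
Zbed4	0.93	0.84	0.78	0.8	0.54	0.7	0.64	1
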