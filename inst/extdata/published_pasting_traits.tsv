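trait	mean	sd	min	max	genetic_var	residual_var	h2	f_value
PV	1200.22	334.56	494.5	2272	115459.13	50143.19	0.70	2.11
TV	1004.04	225.29	463.5	1737	63071.08	18425.03	0.77	2.28
BD	196.18	141.77	2.5	783.5	15269.62	11891.91	0.56	1.96
FV	1980.36	427.17	920	3411	155519.10	99828.04	0.61	2.12
SB	976.33	314.40	319	1930	108176.00	41637.66	0.72	2.40
PT	5.46	0.42	4.6	7	0.11	0.13	0.46	3.26
PTP	81.24	2.14	75.55	87.28	3.40	2.86	0.54	2.71
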