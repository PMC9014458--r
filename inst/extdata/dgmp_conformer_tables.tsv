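n_waters	label	delta_g	vde	ade	x_m
1	manual-9	2.5	1.63	1.20	0.01
1	one-m1	2.2	1.59	1.31	0.02
1	one-m2	1.6	1.64	1.33	0.05
1	one-m5	2.6	1.65	1.36	0.01
1	one-m7	2.0	1.65	1.33	0.02
1	one-m9	2.0	1.36	1.18	0.03
1	one-m12	2.6	1.59	1.31	0.01
1	one-m14	1.9	1.36	0.97	0.03
1	one-m17	1.6	1.67	1.35	0.05
1	one-m18	2.6	1.65	1.36	0.01
1	one-m20	2.0	1.70	1.38	0.03
1	one-m23	0.0	1.70	1.37	0.71
1	one-m29	2.3	1.33	0.97	0.02
2	two-m3	1.4	2.00	1.62	0.04
2	two-m5	1.9	1.81	1.46	0.02
2	two-m6	2.0	1.74	1.42	0.01
2	two-m19	0.0	1.81	1.32	0.46
2	two-m22	2.1	1.75	1.42	0.01
2	two-m23	0.1	1.81	1.53	0.39
2	two-m24	1.7	2.07	1.68	0.03
3	three-m1	0.2	2.17	1.76	0.13
3	three-m2	0.2	2.17	1.76	0.13
3	three-m3	0.5	2.17	1.77	0.08
3	three-m4	0.2	2.09	1.72	0.12
3	three-m5	0.2	2.11	1.72	0.12
3	three-m6	0.4	2.08	1.71	0.09
3	three-m13	0.3	2.08	1.71	0.11
3	three-m15	0.0	2.07	1.69	0.18
3	three-m21	1.4	2.37	1.93	0.02
4	four-m1	1.6	2.23	1.76	0.03
4	four-m3	2.0	2.13	1.75	0.01
4	four-m4	1.1	2.14	1.76	0.06
4	four-m5	1.7	2.14	1.76	0.02
4	four-m8	1.6	2.18	1.79	0.03
4	four-m13	0.7	2.39	1.97	0.12
4	four-m14	1.1	2.17	1.79	0.06
4	four-m15	1.1	2.25	1.84	0.06
4	four-m16	0.8	2.12	1.75	0.10
4	four-m23	0.0	2.34	1.90	0.38
4	four-m27	1.7	2.24	1.82	0.02
4	four-m31	0.8	2.37	1.97	0.10
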