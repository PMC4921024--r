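gene_id	cdd_id	gene_start	gene_end	cdd_start	cdd_end	e_value	pct_identity
g1	cddA	10	190	1	181	1e-20	62.5
g1	cddB	351	650	1	300	1e-30	70.0
g2	cddX	100	165	1	66	1e-08	41.0
g2	cddY	300	375	1	76	1e-09	44.5
g3	cddC	20	159	1	140	1e-25	58.0
g3	cddD	240	389	1	150	1e-22	61.0
g4	cddA	4	188	1	185	1e-40	88.0
g5	cddB	6	305	1	300	1e-45	91.0
g6	cddC	3	142	1	140	1e-35	84.0
g7	cddD	4	153	1	150	1e-33	80.5
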