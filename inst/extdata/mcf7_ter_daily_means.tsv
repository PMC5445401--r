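cell_line	day5_mean	day5_sem	day6_mean	day6_sem	day7_mean	day7_sem	combined_printed
MT3	35.32	5.81	53.57	13.88	52.27	12.11	48.72
MT3dCT	41.99	9.26	53.08	9.57	47.67	5.16	47.58
MT3dNT	26.39	1.99	44.06	3.37	28.16	5.87	32.87
MT1E	32.68	7.26	35.92	6.98	30.91	8.41	33.17
MT1E-CT	22.96	11.94	29.34	9.40	37.98	7.07	30.09
MT1E-NT	37.58	10.23	34.30	9.40	32.28	12.61	34.72
parent	38.80	12.10	22.21	4.63	32.40	1.92	31.13
blank_vector	41.99	5.38	27.38	10.76	36.80	6.48	35.39
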