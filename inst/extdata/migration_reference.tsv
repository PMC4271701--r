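breed	bta	region_start_mb	region_end_mb	freq_parental	expected	observed	freq_change	z
HOL	4	49.22	57.03	0.43	0.11	0.29	-0.18	-3.11
GNS	6	62.96	64.29	0.50	0.21	0.09	0.12	3.94
HOL	10	51.97	66.12	0.34	0.25	0.05	-0.20	-4.08
HOL	13	28.92	34.03	0.44	0.29	0.05	-0.24	-5.00
GNS	13	49.86	51.78	0.67	0.19	0.09	0.10	3.40
HOL	16	43.30	45.76	0.16	0.07	0.34	0.27	7.83
GNS	16	44.05	45.76	0.52	0.19	0.34	-0.15	-3.66
GNS	24	34.81	39.06	0.48	0.18	0.06	0.12	4.03
HOL	26	22.31	24.91	0.52	0.25	0.34	0.09	3.13
NRC	26	22.31	24.91	0.45	0.18	0.33	-0.15	-3.62
NRC	26	37.33	39.74	0.38	0.21	0.05	0.16	4.26
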