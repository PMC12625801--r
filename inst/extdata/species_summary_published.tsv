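species	nT	nJ	N	fcsa_mm2	bm_kg	lower95_kg	upper95_kg
Archaeoindris fontoynontii	0	1	1	708.10	127.74	56.95	286.52
Archaeolemur sp.	0	2	2	140.96	16.70	7.84	35.56
Archaeolemur edwardsi	6	8	14	162.55	20.01	9.36	42.78
Archaeolemur majori	14	3	17	116.77	13.20	6.22	27.99
Babakotia radofilai	0	4	4	106.92	11.80	5.57	24.96
Daubentonia robusta	0	2	2	92.66	9.84	4.66	20.76
Megaladapis edwardsi	6	6	12	413.30	64.97	29.53	142.91
Megaladapis grandidieri	1	5	6	367.80	56.10	25.60	122.91
Megaladapis madagascariensis	2	6	8	233.04	31.56	14.61	68.16
Mesopropithecus dolichobrachion	0	1	1	79.31	8.09	3.84	17.01
Mesopropithecus globiceps	3	6	9	70.79	7.02	3.34	14.73
Mesopropithecus pithecoides	1	0	1	87.40	9.14	4.34	19.26
Pachylemur insignis	25	9	34	80.98	8.33	3.96	17.53
Pachylemur jullyi	0	4	4	91.99	9.75	4.62	20.58
Paleopropithecus ingens	1	3	4	224.91	30.32	14.04	65.46
Paleopropithecus maximus	5	3	8	225.60	30.29	14.04	65.34
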