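India_GJ	0	1334	972	1272	1670	3001	3395	3134	3396	3948	3691	5079	3740	5260	4823	7723	7443	7693	4917	4627
India_South	-0.04	0	2156	1508	1807	2379	2920	2721	3130	3270	2962	4306	2731	4139	4620	8319	8127	8344	5042	4699
India_PB	0.11	0.26	0	1260	1528	3097	3336	3059	3184	3991	3796	5130	4070	5628	4455	8034	7691	7961	5612	5356
India_JK	0.26	0.40	0.40	0	558	1855	2166	1895	2127	2777	2559	3920	2814	4372	3555	8988	8697	8951	6126	5818
Bangladesh	0.01	0.13	-0.09	0.34	0	1580	1818	1542	1737	2463	2273	3602	2636	4181	3151	9379	9080	9337	6528	6218
Thailand	-0.02	0.04	0.03	0.30	-0.02	0	587	523	999	948	704	2081	1184	2650	2352	10638	10401	10637	7417	7071
Laos_SK	-0.04	-0.01	0.09	0.33	0.01	0.02	0	277	512	711	686	1806	1494	2742	1765	11099	10836	11082	7961	7619
Laos_VN	-0.001	0.05	-0.004	0.34	-0.06	0.01	-0.01	0	480	971	888	2081	1614	2954	1912	10847	10577	10825	7754	7416
Vietnam_North	0.11	0.18	-0.06	0.38	-0.03	0.05	0.12	0.05	0	1136	1185	2103	2006	3210	1493	11115	10817	11074	8133	7802
Vietnam_BinhThuan	0.15	0.25	-0.06	0.41	-0.02	0.08	0.16	0.07	-0.02	0	324	1143	1113	2078	1843	11560	11344	11576	8273	7920
Vietnam_AnGiang	0.10	0.19	-0.06	0.38	-0.05	0.03	0.11	0.03	-0.02	-0.02	0	1389	871	2066	2117	11272	11056	11284	7953	7600
Malaysia_East	0.45	0.60	0.11	0.57	0.22	0.30	0.40	0.27	0.09	0.05	0.12	0	1708	1612	1990	12623	12428	12649	9202	8843
Malaysia_West	0.29	0.36	0.02	0.50	0.10	0.20	0.29	0.18	0.04	0.02	0.06	-0.03	0	1558	2956	10982	10829	11032	7502	7141
Indonesia_JV	0.65	0.74	0.38	0.71	0.50	0.48	0.56	0.46	0.27	0.25	0.33	0.03	0.11	0	3562	12085	12017	12183	8468	8107
Taiwan	0.02	0.07	-0.01	0.40	-0.05	0.01	0.03	-0.01	0.04	0.06	0.02	0.29	0.18	0.47	0	12484	12144	12415	9623	9294
Benin_South	0.60	0.67	0.54	0.68	0.55	0.59	0.60	0.54	0.52	0.53	0.55	0.57	0.52	0.64	0.58	0	514	286	3640	3995
Benin_North	0.61	0.72	0.54	0.66	0.54	0.59	0.61	0.54	0.51	0.52	0.55	0.58	0.52	0.68	0.60	-0.02	0	291	3671	4012
Benin_Central	0.52	0.64	0.44	0.61	0.44	0.52	0.53	0.46	0.44	0.44	0.47	0.49	0.45	0.60	0.52	-0.02	-0.01	0	3778	4127
Kenya_NYZ	0.82	0.84	0.79	0.85	0.80	0.77	0.76	0.74	0.71	0.74	0.77	0.80	0.71	0.82	0.74	0.14	0.12	0.26	0	363
Kenya_Eastern	0.78	0.82	0.74	0.81	0.75	0.73	0.73	0.70	0.67	0.69	0.72	0.76	0.67	0.79	0.71	0.09	0.07	0.19	-0.01	0
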