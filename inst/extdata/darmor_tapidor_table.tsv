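name	darmor_snps	darmor_length_mbp	darmor_snps_per_mbp	tapidor_snps	tapidor_length_mbp	tapidor_snps_per_mbp	darmor_genes	tapidor_genes	tapidor_absent_in_darmor	darmor_absent_in_tapidor
chrA01	45870	31.16	1472	37875	23.9	1586	3687	3050	0	3
chrA02	45229	31.34	1443	46599	27.9	1672	3528	3315	1	0
chrA03	59180	39.49	1499	55319	32.1	1723	5429	4408	0	4
chrA04	57270	23.31	2457	49357	21	2351	2676	2638	0	0
chrA05	54784	28.6	1916	36548	20.1	1818	3506	2634	1	1
chrA06	72163	31.9	2262	57613	29.1	1977	3926	3713	0	0
chrA07	45458	28.9	1573	34101	22.7	1505	3555	2976	0	0
chrA08	24807	21.74	1141	22096	16.4	1346	2827	2147	0	0
chrA09	79586	46.72	1704	53008	30.8	1721	5286	3913	0	3
chrA10	27723	19.96	1389	35378	22.5	1575	2800	3175	0	1
chrC01	92316	47.95	1925	63462	31.9	1990	3739	3083	0	5
chrC02	49665	58.66	847	47872	40.5	1181	4182	3572	1	23
chrC03	64224	71.85	894	72229	55.2	1307	6448	5800	0	9
chrC04	95329	61.04	1562	79006	45.6	1733	4658	4356	0	2
chrC05	25226	52.72	479	43752	45.6	959	4452	4839	0	4
chrC06	41036	44.61	920	41252	34.1	1211	3543	3230	0	6
chrC07	34089	52.5	649	41001	37.3	1099	4165	3523	0	1
chrC08	43857	46.29	947	48079	40.2	1197	4140	4295	0	0
chrC09	46660	60.21	775	57479	51	1127	4607	4864	0	2
unplaced	2513	51.33	49	23380	8.5	2752	3228	631	0	9
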