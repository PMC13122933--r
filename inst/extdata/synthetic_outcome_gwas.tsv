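rsid	chromosome	base_pair_location	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n	n_cases	n_controls
rs0000001	1	1000001	A	G	0.3847770161926746	-0.0062324221678343155	0.009430448725193085	0.5086874222682357	500000	25000	475000
rs0000002	2	1000002	A	G	0.17834701305255296	0.01395125441426916	0.011986049196142948	0.24444114906628941	500000	25000	475000
rs0000003	3	1000003	A	G	0.32214533127844336	0.022715542751399795	0.009818812765191655	0.020696734110759632	500000	25000	475000
rs0000004	4	1000004	A	G	0.32926924964413046	-0.014842508583184338	0.009763454337472863	0.12845800767012652	500000	25000	475000
rs0000005	5	1000005	A	G	0.23280368596315387	0.029915577275432863	0.010856879441162178	0.005861164657082204	500000	25000	475000
rs0000006	7	1000006	A	G	0.3305681224912405	0.015895545132235026	0.009753702727620907	0.10316630926288255	500000	25000	475000
rs0000007	8	1000007	A	G	0.21628439743071798	0.013311792959055218	0.011144519622340341	0.23229421797103647	500000	25000	475000
rs0000008	9	1000008	A	G	0.17128365114331245	0.012246488968762266	0.0121784575280803	0.3146146593689586	500000	25000	475000
rs0000009	10	1000009	A	G	0.4006352281197906	0.05173864932625232	0.009363388026606804	3.2829907253934936e-8	500000	25000	475000
rs0000010	11	1000010	A	G	0.09761929288506509	0.03244399891098479	0.015459322802764927	0.03584610413554835	500000	25000	475000
rs0000011	12	1000011	A	G	0.4107531403191388	0.013402197577554741	0.009326401560386695	0.15071316357878975	500000	25000	475000
rs0000012	13	1000012	A	G	0.4312431731261313	0.008391072626668206	0.00926464467162048	0.36508986525611364	500000	25000	475000
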