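rsid	chromosome	base_pair_location	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n	n_cases	n_controls
rs0000001	1	1000001	A	G	0.3847770161926746	0.11820566741465342	0.009688865029310198	3.102280205699286e-34	250000	25000	225000
rs0000002	2	1000002	A	G	0.17834701305255296	0.17002731242296149	0.012314494917496439	2.309821885053356e-43	250000	25000	225000
rs0000003	3	1000003	A	G	0.32214533127844336	0.10203891868712026	0.010087871150379662	4.739680801455212e-24	250000	25000	225000
rs0000004	4	1000004	A	G	0.32926924964413046	0.08981706093976409	0.010030995772544318	3.4297606241634127e-19	250000	25000	225000
rs0000005	5	1000005	A	G	0.23280368596315387	0.1203858692726198	0.01115438327594102	3.726925025299562e-27	250000	25000	225000
rs0000006	7	1000006	A	G	0.3305681224912405	0.08475569799115511	0.010020976945823837	2.7240382702909932e-17	250000	25000	225000
rs0000007	8	1000007	A	G	0.21628439743071798	0.047061981491247934	0.01144990546938622	3.952298525588282e-5	250000	25000	225000
rs0000008	9	1000008	A	G	0.17128365114331245	0.12351650733229981	0.012512175686776855	5.5217926862612e-23	250000	25000	225000
rs0000009	10	1000009	A	G	0.4006352281197906	0.2685990710157152	0.009619966711074505	1.4836986297792985e-171	250000	25000	225000
rs0000010	11	1000010	A	G	0.09761929288506509	0.10074619185932562	0.01588294432696362	2.2527116256600932e-10	250000	25000	225000
rs0000011	12	1000011	A	G	0.4107531403191388	0.06230064600311357	0.009581966729359908	7.933072498453459e-11	250000	25000	225000
rs0000012	13	1000012	A	G	0.4312431731261313	0.08660949918517599	0.009518517557711536	9.11225682184279e-20	250000	25000	225000
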