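species	brood_id	n_male	n_female	mother_wolbachia
Armadillidium_depressum	synb1	12	38	negative
Armadillidium_depressum	synb2	13	37	negative
Armadillidium_depressum	synb3	11	39	negative
Armadillidium_depressum	synb4	12	38	negative
Armadillidium_depressum	synb5	12	38	negative
Armadillidium_depressum	synb6	12	38	negative
Armadillidium_granulatum	synb7	12	38	negative
Armadillidium_granulatum	synb8	11	39	negative
Armadillidium_granulatum	synb9	13	37	negative
Armadillidium_granulatum	synb10	12	38	negative
Armadillidium_maculatum	synb11	12	38	negative
Armadillidium_maculatum	synb12	12	38	negative
Armadillidium_maculatum	synb13	11	39	negative
Armadillidium_maculatum	synb14	13	37	negative
Porcellio_scaber	synb15	9	21	negative
Armadillidium_nasatum	synb16	0	35	negative
Armadillidium_nasatum	synb17	0	40	negative
Armadillidium_nasatum	synb18	0	30	negative
Armadillo_officinalis	synb19	0	30	negative
Armadillo_officinalis	synb20	0	28	negative
Armadillo_officinalis	synb21	0	33	negative
Armadillidium_assimile	synb22	25	0	negative
Armadillidium_assimile	synb23	30	0	negative
Armadillidium_assimile	synb24	28	0	negative
Armadillidium_assimile	synb25	32	0	negative
Armadillidium_assimile	synb26	27	0	negative
Armadillidium_assimile	synb27	30	0	negative
Armadillidium_simoni	synb28	10	12	negative
Armadillidium_simoni	synb29	11	9	negative
Armadillidium_siculorum	synb30	8	10	negative
Armadillidium_siculorum	synb31	15	13	negative
Armadillidium_siculorum	synb32	9	9	negative
Armadillidium_versicolor	synb33	7	9	negative
Armadillidium_versicolor	synb34	12	10	negative
Porcellio_dispar	synb35	14	12	negative
Porcellio_dispar	synb36	6	8	negative
Armadillidium_depressum	synb37	5	7	negative
Porcellio_scaber	synb38	8	6	negative
Armadillidium_depressum	synb39	3	32	positive
Armadillidium_depressum	synb40	5	38	positive
Armadillidium_granulatum	synb41	2	28	positive
Porcellio_scaber	synb42	4	30	positive
Armadillidium_versicolor	synb43	3	25	positive
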