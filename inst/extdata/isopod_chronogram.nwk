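(Cherax_quadricarinatus:390,(Talitrus_saltator:350,(Asellus_aquaticus:307,(Helleria_brevicornis:117,(Armadillo_officinalis:66,((Chaetophiloscia_elongata:36,(Philoscia_muscorum:15,Oniscus_asellus:15)PO:21)PHI:20.667,((Eluma_purpurascens:36.167,(Armadillidium_nasatum:25,(Armadillidium_vulgare:20.833,(Armadillidium_tunisiense:16.667,((Armadillidium_versicolor:8.333,(Armadillidium_siculorum:4.167,Armadillidium_assimile:4.167)a5:4.166)a4:4.167,(Armadillidium_granulatum:9.375,(Armadillidium_depressum:6.25,(Armadillidium_simoni:3.125,Armadillidium_maculatum:3.125)a8:3.125)a7:3.125)a6:3.125)a3:4.167)a2:4.166)a1:4.167)A25:11.167)ARM:11.166,(Trachelipus_rathkei:38,(Porcellionides_pruinosus:36.5,(Porcellio_laevis:35,(Porcellio_dispar:26.25,(Porcellio_scaber:17.5,(Porcellio_dilatatus_dilatatus:8.75,Porcellio_dilatatus_petiti:8.75)p3:8.75)p2:8.75)p1:8.75)POR:1.5)PORF:1.5)TRA:9.333)NC:9.334)NB:9.333)N66:51)ONI:190)ISO:43)OUT1:40)OUT2;
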