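species	state
Armadillidium_maculatum	ZW
Armadillidium_simoni	UNKNOWN
Armadillidium_depressum	ZW
Armadillidium_granulatum	ZW
Armadillidium_siculorum	UNKNOWN
Armadillidium_assimile	OTHER
Armadillidium_versicolor	UNKNOWN
Armadillidium_vulgare	ZW
Armadillidium_tunisiense	UNKNOWN
Armadillidium_nasatum	XY
Eluma_purpurascens	ZW
Porcellio_dilatatus_petiti	ZW
Porcellio_dilatatus_dilatatus	XY
Porcellio_dispar	UNKNOWN
Porcellio_scaber	ZW
Porcellio_laevis	ZW
Porcellionides_pruinosus	UNKNOWN
Trachelipus_rathkei	ZW
Oniscus_asellus	ZW
Philoscia_muscorum	UNKNOWN
Chaetophiloscia_elongata	UNKNOWN
Armadillo_officinalis	XY
Helleria_brevicornis	XY
Asellus_aquaticus	XY
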