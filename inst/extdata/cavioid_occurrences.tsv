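taxon	fad_max	fad_min	interval
Asteromys_punctus			Deseadan
Chubutomys_simpsoni			Deseadan
Luantus_initialis			Colhuehuapian
Luantus_minor			Colhuehuapian
Chubutomys_leucoreios			Colhuehuapian
Luantus_propheticus			Colhuehuapian
Luantus_toldensis			Santacrucian
Phanomys_mixtus			Santacrucian
Phanomys_vetulus			Santacrucian
Eocardia_montana			Santacrucian
Eocardia_fissa			Santacrucian
Eocardia_excavata			Santacrucian
Schistomys_erro			Santacrucian
Schistomys_rollinsi			Santacrucian
Matiamys_elegans			Colloncuran
Eocardia_robertoi			Colloncuran
Eocardia_robusta			Colloncuran
Guiomys_unica			Colloncuran
Microcardiodon			Colloncuran
Prodolichotis_pridiana			Laventan
Cardiatherium_chasicoense			Chasicoan
Cardiomys_cavinus			Chasicoan
Procardiomys_martinoi			Chasicoan
Paleocavia_impar			Montehermosan
Dolicavia_minuscula			Chapadmalan
Microcavia_chapalmalensis			Chapadmalan
Galea_musteloides	0	0
Cavia_aperea	0	0
Microcavia_australis	0	0
Dolichotis_patagonum	0	0
Kerodon_rupestris	0	0
Hydrochoerus_hydrochaeris	0	0
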