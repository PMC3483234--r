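(Asteromys_punctus,(Luantus_initialis,(Luantus_minor,(Chubutomys_leucoreios,(Chubutomys_simpsoni,(Luantus_propheticus,(Luantus_toldensis,((Phanomys_mixtus,Phanomys_vetulus),(Eocardia_montana,Eocardia_fissa,(Matiamys_elegans,((Eocardia_excavata,Schistomys_erro),(Eocardia_robertoi,(Schistomys_rollinsi,(Eocardia_robusta,(Guiomys_unica,(Microcardiodon,((Galea_musteloides,(Cavia_aperea,(Dolicavia_minuscula,Paleocavia_impar,(Microcavia_australis,Microcavia_chapalmalensis)))),(Dolichotis_patagonum,(Prodolichotis_pridiana,(Kerodon_rupestris,(Cardiatherium_chasicoense,Cardiomys_cavinus,Procardiomys_martinoi,Hydrochoerus_hydrochaeris)))))))))))))))))))));
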