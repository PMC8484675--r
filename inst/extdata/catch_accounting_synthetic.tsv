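classification	rank	biomass_kg	detected
Scomber japonicus	species	255000	0
Scomber australasicus	species	1200	0
Parapristipoma trilineatum	species	12000	1
Trachurus japonicus	species	15000	1
Pagrus major	species	8000	1
Engraulis japonicus	species	9000	1
Sardinops melanostictus	species	6000	1
Seriola quinqueradiata	species	4500	1
Lateolabrax japonicus	species	500	1
Etrumeus teres	species	800	1
Thamnaconus modestus	species	400	1
Oplegnathus fasciatus	species	300	1
Dentex tumifrons	species	250	1
Semicossyphus reticulatus	species	120	1
Girella punctata	species	90	1
Sacura margaritacea	species	60	1
Chelidonichthys spinosus	species	45	1
Sphyraena pinguis	species	30	1
Konosirus punctatus	species	25	1
Mugil cephalus	species	700	0
Kyphosus vaigiensis	species	40	0
Stephanolepis cirrhifer	species	35	0
Pennahia argentata	species	20	0
Sillago japonica	species	15	0
Halichoeres poecilopterus	species	8	1
Pseudolabrus sieboldi	species	5	1
Chaenogobius annularis	species	2	1
Parablennius yatabei	species	1.5	1
Fistularia commersonii	species	9	0
Upeneus japonicus	species	7	0
Apogon semilineatus	species	6	0
Hyporhamphus sajori	species	5	0
Takifugu niphobles	species	4	0
Pempheris japonica	species	3	0
Ditrema temminckii	species	2.5	0
Hypodytes rubripinnis	species	2	0
Rudarius ercodes	species	1	0
Aulichthys japonicus	species	0.5	0
Seriola sp.	genus	150	0
Fistulariidae	family	0.2	0
Carangidae	family	75	0
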