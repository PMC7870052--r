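family,species,trophic_group,pelagic,present_at_control
Myliobatidae,Myliobatis aquila,MACRO,FALSE,TRUE
Clupeidae,Sarda sarda,PISC,TRUE,FALSE
Engraulidae,Engraulis encrasicolus,PLAN,TRUE,TRUE
Muraenidae,Muraena helena,PISC,FALSE,TRUE
Belonidae,Belone belone,PISC,TRUE,FALSE
Phycidae,Phycis phycis,PISC,FALSE,TRUE
Serranidae,Anthias anthias,PLAN,TRUE,TRUE
Serranidae,Epinephelus costae,PISC,FALSE,TRUE
Serranidae,Epinephelus marginatus,PISC,FALSE,TRUE
Serranidae,Epinephelus caninus,PISC,FALSE,FALSE
Serranidae,Mycteroperca rubra,PISC,FALSE,TRUE
Serranidae,Serranus atricauda,MACRO,FALSE,TRUE
Serranidae,Serranus cabrilla,MACRO,FALSE,TRUE
Serranidae,Serranus scriba,MACRO,FALSE,TRUE
Moronidae,Dicentrarchus labrax,PISC,FALSE,TRUE
Apogonidae,Apogon imberbis,MICRO,FALSE,TRUE
Carangidae,Seriola dumerili,PISC,TRUE,TRUE
Carangidae,Trachurus spp.,PLAN,TRUE,FALSE
Carangidae,Pseudocaranx dentex,PLAN,TRUE,FALSE
Scombridae,Sarpa salpa,HERB,FALSE,TRUE
Scombridae,Euthynnus alletteratus,PISC,TRUE,TRUE
Coryphaenidae,Coryphaena hippurus,PISC,TRUE,FALSE
Haemulidae,Pomadasys incisus,MACRO,FALSE,TRUE
Haemulidae,Parapristipoma octolineatum,MACRO,FALSE,TRUE
Sciaenidae,Sciaena umbra,PISC,FALSE,TRUE
Mullidae,Mullus surmuletus,DETR,FALSE,TRUE
Sparidae,Boops boops,PLAN,TRUE,TRUE
Sparidae,Dentex dentex,PISC,FALSE,TRUE
Sparidae,Diplodus annularis,OMNI,FALSE,TRUE
Sparidae,Diplodus cervinus,OMNI,FALSE,TRUE
Sparidae,Diplodus puntazzo,OMNI,FALSE,TRUE
Sparidae,Diplodus sargus,OMNI,FALSE,TRUE
Sparidae,Diplodus vulgaris,OMNI,FALSE,TRUE
Sparidae,Oblada melanura,PLAN,TRUE,TRUE
Sparidae,Pagrus pagrus,OMNI,FALSE,TRUE
Sparidae,Pagrus auriga,OMNI,FALSE,FALSE
Sparidae,Sardina pilchardus,PLAN,TRUE,TRUE
Sparidae,Sparus aurata,OMNI,FALSE,TRUE
Sparidae,Spondyliosoma cantharus,OMNI,FALSE,TRUE
Sparidae,Spicara smaris,PLAN,TRUE,TRUE
Sparidae,Spicara maena,PLAN,TRUE,TRUE
Pomacentridae,Chromis chromis,PLAN,TRUE,TRUE
Labridae,Coris julis,MICRO,FALSE,TRUE
Labridae,Labrus merula,MICRO,FALSE,TRUE
Labridae,Labrus viridis,MICRO,FALSE,TRUE
Labridae,Symphodus doderleini,MICRO,FALSE,TRUE
Labridae,Symphodus mediterraneus,MICRO,FALSE,TRUE
Labridae,Symphodus melanocercus,MICRO,FALSE,TRUE
Labridae,Symphodus ocellatus,MICRO,FALSE,TRUE
Labridae,Symphodus roissali,MICRO,FALSE,TRUE
Labridae,Symphodus cinereus,MICRO,FALSE,TRUE
Labridae,Symphodus rostratus,MICRO,FALSE,TRUE
Labridae,Symphodus tinca,MICRO,FALSE,TRUE
Labridae,Thalassoma pavo,MICRO,FALSE,TRUE
Sphyraenidae,Sphyraena viridensis,PISC,TRUE,TRUE
Mugilidae,Mugilidae spp.,DETR,TRUE,TRUE
Scorpaenidae,Scorpaena maderensis,MACRO,FALSE,FALSE
Scorpaenidae,Scorpaena scrofa,PISC,FALSE,TRUE
Scorpaenidae,Scorpaena porcus,MACRO,FALSE,TRUE
Scorpaenidae,Scorpaena notata,MACRO,FALSE,TRUE
Atherinidae,Atherina sp.,PLAN,TRUE,FALSE
Molidae,Mola mola,PLAN,TRUE,FALSE
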