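"species","total","n_strata","ccc_hlc_outdoor","ccc_shk_indoor","ccc_shk_outdoor"
"Anopheles funestus s.l",81,20,0.579,0.531,0.486
"Anopheles gambiae s.l",8712,35,0.487,0.488,0.509
"Anopheles pharoensis",2442,34,0.551,0.56,0.497
"Anopheles tenebrosus",1087,31,0.477,0.454,0.595
"Anopheles ziemanni",1531,25,0.534,0.5,0.596
"Aedes fryeri",218,12,0.331,0.401,0.613
"Aedes sudanensis",5,5,0,0.5,0.5
"Aedes subargenteus",4,NA,NA,NA,NA
"Culex antennatus",2227,16,0.503,0.523,0.546
"Culex bitaeniorhynchus",17,7,0.746,1,0.5
"Culex pipiens",6618,30,0.587,0.503,0.598
"Culex poicilipes",6504,35,0.517,0.327,0.492
"Culex quinquefasciatus",88,14,0.528,0.6,0.595
"Culex sitiens",4,3,0.25,0.5,1
"Culex tritaeniorhynchus",11021,34,0.447,0.425,0.453
"Coquillettidia aurites",13,7,0.306,0.377,0.5
"Coquillettidia versicolor",1,1,1,NA,NA
"Mansonia africana",5482,35,0.665,0.345,0.583
"Mansonia uniformis",51062,35,0.479,0.449,0.587
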