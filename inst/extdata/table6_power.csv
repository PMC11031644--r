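"species","hlc_outdoor_alpha","hlc_outdoor_alpha_lo","hlc_outdoor_alpha_hi","hlc_outdoor_gamma","hlc_outdoor_gamma_lo","hlc_outdoor_gamma_hi","shk_indoor_alpha","shk_indoor_alpha_lo","shk_indoor_alpha_hi","shk_indoor_gamma","shk_indoor_gamma_lo","shk_indoor_gamma_hi","shk_outdoor_alpha","shk_outdoor_alpha_lo","shk_outdoor_alpha_hi","shk_outdoor_gamma","shk_outdoor_gamma_lo","shk_outdoor_gamma_hi"
"Anopheles funestus s.l",4.71,0.46,211.96,0.23,0.02,0.58,0.25,0.14,0.45,1.37,0.71,2.31,0.01,0,0.11,0.89,0.3,2.01
"Anopheles gambiae s.l",0.26,0.2,0.33,1.43,1.31,1.54,1.22,0.54,4.1,0.68,0.53,0.8,0.2,0.06,2.08,0.5,0.28,0.72
"Anopheles pharoensis",NA,NA,NA,NA,NA,NA,0.64,0.52,0.83,17.62,13.5,24,2.14,1.42,4.66,3.31,2.8,3.92
"Anopheles tenebrosus",16.23,8.28,46.88,1.14,0.82,1.53,0.03,0,0.3,0.98,0.36,2.23,1.33,0.84,2.25,1.27,0.7,2.02
"Anopheles ziemanni",10.06,4.23,23.9,1.25,1.03,1.45,0.01,0,0.08,1.94,0.55,4.98,0.86,0.52,1.61,1.3,0.92,1.75
"Aedes fryeri",NA,NA,NA,NA,NA,NA,1.82,0.69,5.77,1.49,0.81,2.49,4.67,1.61,12.3,1.9,1.3,2.69
"Culex antennatus",1.42,0.49,6.16,1.44,1.1,1.88,6.59,0.73,128.02,0.44,0.23,0.7,NA,NA,NA,NA,NA,NA
"Culex pipiens",0.21,0.18,0.24,2.24,2.12,2.38,0.32,0.21,0.56,1.06,0.89,1.23,0.12,0.09,0.16,1.46,1.24,1.71
"Culex poicilipes",2.39,1.41,4.12,1.09,1.04,1.17,0.05,0.04,0.06,2.14,1.83,2.47,0.37,0.25,0.59,1.15,1.01,1.28
"Culex quinquefasciatus",0.13,0,4.76,0.28,0.01,0.91,7.31,0.47,607.6,0.35,0.11,1.05,0.01,0,0.16,0.42,0.1,1.03
"Culex tritaeniorhynchus",0.57,0.4,0.72,1.94,1.8,2.27,0.13,0.1,0.17,1.96,1.75,2.39,0.33,0.24,0.43,1.78,1.64,2.05
"Mansonia africana",0.24,0.18,0.33,1.65,1.43,1.87,267.22,10.53,11255.65,0.29,0.22,0.4,0.48,0.29,0.99,1,0.84,1.18
"Mansonia uniformis",3.06,2.36,4.33,0.92,0.89,0.95,1.46,1.03,2.28,0.8,0.76,0.85,0.08,0.07,0.09,1.77,1.7,1.83
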