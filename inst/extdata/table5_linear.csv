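"species","hlc_outdoor","hlc_outdoor_lo","hlc_outdoor_hi","shk_indoor","shk_indoor_lo","shk_indoor_hi","shk_outdoor","shk_outdoor_lo","shk_outdoor_hi","ratio_out_in","dic_linear","dic_power"
"Anopheles funestus s.l",0.72,0.44,1.18,0.27,0.13,0.52,0.02,0,0.12,0.09,182.76,175.26
"Anopheles gambiae s.l",1.31,1.25,1.37,0.21,0.2,0.23,0.04,0.04,0.05,0.2,2577.69,2414.28
"Anopheles pharoensis",68.28,49.07,99.8,4.4,3.02,6.54,11.82,8.28,17.39,2.69,1734.84,1210.9
"Anopheles tenebrosus",40.08,27.66,62.22,0.04,0,0.18,1.47,0.89,2.47,39.01,419.11,419.13
"Anopheles ziemanni",26.92,20.62,35.96,0,0,0.05,1.23,0.85,1.78,277.41,403.86,404.81
"Aedes fryeri",16.05,7.35,37.18,2.97,1.14,7.95,27.98,12.85,65.79,9.41,202.98,121.1
"Culex antennatus",7.08,6.17,8.14,0.39,0.31,0.5,1.23,1.03,1.46,3.12,1602.21,1428.78
"Culex pipiens",4.88,4.57,5.21,0.35,0.3,0.39,0.27,0.23,0.31,0.78,3156.33,2689.15
"Culex poicilipes",3.65,3.42,3.87,0.15,0.12,0.17,0.54,0.5,0.6,3.75,2158.39,2094.89
"Culex quinquefasciatus",0.21,0.09,0.41,0.78,0.5,1.2,0.07,0.02,0.19,0.09,201.9,194.32
"Culex tritaeniorhynchus",7.45,7.01,7.97,0.54,0.49,0.6,1.95,1.81,2.1,3.59,4543.6,4403.45
"Mansonia africana",1.71,1.6,1.83,0.34,0.3,0.37,0.56,0.52,0.62,1.68,2778.16,2638.87
"Mansonia uniformis",1.79,1.74,1.83,0.49,0.47,0.51,1.3,1.27,1.33,2.66,14708.76,13024.37
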