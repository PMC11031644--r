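"species","method","location","site","night","count"
"Anopheles funestus s.l","HLC","indoor","massavasse","aggregate",40
"Anopheles funestus s.l","HLC","outdoor","massavasse","aggregate",29
"Anopheles funestus s.l","SHK","indoor","massavasse","aggregate",11
"Anopheles funestus s.l","SHK","outdoor","massavasse","aggregate",1
"Anopheles gambiae s.l","HLC","indoor","massavasse","aggregate",3403
"Anopheles gambiae s.l","HLC","outdoor","massavasse","aggregate",4437
"Anopheles gambiae s.l","SHK","indoor","massavasse","aggregate",725
"Anopheles gambiae s.l","SHK","outdoor","massavasse","aggregate",147
"Anopheles pharoensis","HLC","indoor","massavasse","aggregate",28
"Anopheles pharoensis","HLC","outdoor","massavasse","aggregate",1950
"Anopheles pharoensis","SHK","indoor","massavasse","aggregate",126
"Anopheles pharoensis","SHK","outdoor","massavasse","aggregate",338
"Anopheles tenebrosus","HLC","indoor","massavasse","aggregate",25
"Anopheles tenebrosus","HLC","outdoor","massavasse","aggregate",1023
"Anopheles tenebrosus","SHK","indoor","massavasse","aggregate",1
"Anopheles tenebrosus","SHK","outdoor","massavasse","aggregate",38
"Anopheles ziemanni","HLC","indoor","massavasse","aggregate",53
"Anopheles ziemanni","HLC","outdoor","massavasse","aggregate",1413
"Anopheles ziemanni","SHK","indoor","massavasse","aggregate",0
"Anopheles ziemanni","SHK","outdoor","massavasse","aggregate",65
"Aedes fryeri","HLC","indoor","massavasse","aggregate",4
"Aedes fryeri","HLC","outdoor","massavasse","aggregate",73
"Aedes fryeri","SHK","indoor","massavasse","aggregate",14
"Aedes fryeri","SHK","outdoor","massavasse","aggregate",127
"Aedes sudanensis","HLC","indoor","massavasse","aggregate",1
"Aedes sudanensis","HLC","outdoor","massavasse","aggregate",4
"Aedes sudanensis","SHK","indoor","massavasse","aggregate",0
"Aedes sudanensis","SHK","outdoor","massavasse","aggregate",0
"Aedes subargenteus","HLC","indoor","massavasse","aggregate",0
"Aedes subargenteus","HLC","outdoor","massavasse","aggregate",4
"Aedes subargenteus","SHK","indoor","massavasse","aggregate",0
"Aedes subargenteus","SHK","outdoor","massavasse","aggregate",0
"Culex pipiens","HLC","indoor","massavasse","aggregate",1019
"Culex pipiens","HLC","outdoor","massavasse","aggregate",4971
"Culex pipiens","SHK","indoor","massavasse","aggregate",353
"Culex pipiens","SHK","outdoor","massavasse","aggregate",275
"Culex poicilipes","HLC","indoor","massavasse","aggregate",1219
"Culex poicilipes","HLC","outdoor","massavasse","aggregate",4444
"Culex poicilipes","SHK","indoor","massavasse","aggregate",177
"Culex poicilipes","SHK","outdoor","massavasse","aggregate",664
"Culex tritaeniorhynchus","HLC","indoor","massavasse","aggregate",1007
"Culex tritaeniorhynchus","HLC","outdoor","massavasse","aggregate",7504
"Culex tritaeniorhynchus","SHK","indoor","massavasse","aggregate",547
"Culex tritaeniorhynchus","SHK","outdoor","massavasse","aggregate",1963
"Culex antennatus","HLC","indoor","massavasse","aggregate",229
"Culex antennatus","HLC","outdoor","massavasse","aggregate",1625
"Culex antennatus","SHK","indoor","massavasse","aggregate",91
"Culex antennatus","SHK","outdoor","massavasse","aggregate",282
"Culex quinquefasciatus","HLC","indoor","massavasse","aggregate",43
"Culex quinquefasciatus","HLC","outdoor","massavasse","aggregate",9
"Culex quinquefasciatus","SHK","indoor","massavasse","aggregate",33
"Culex quinquefasciatus","SHK","outdoor","massavasse","aggregate",3
"Culex bitaeniorhynchus","HLC","indoor","massavasse","aggregate",2
"Culex bitaeniorhynchus","HLC","outdoor","massavasse","aggregate",3
"Culex bitaeniorhynchus","SHK","indoor","massavasse","aggregate",1
"Culex bitaeniorhynchus","SHK","outdoor","massavasse","aggregate",11
"Culex sitiens","HLC","indoor","massavasse","aggregate",1
"Culex sitiens","HLC","outdoor","massavasse","aggregate",2
"Culex sitiens","SHK","indoor","massavasse","aggregate",0
"Culex sitiens","SHK","outdoor","massavasse","aggregate",1
"Coquillettidia aurites","HLC","indoor","massavasse","aggregate",1
"Coquillettidia aurites","HLC","outdoor","massavasse","aggregate",8
"Coquillettidia aurites","SHK","indoor","massavasse","aggregate",4
"Coquillettidia aurites","SHK","outdoor","massavasse","aggregate",0
"Coquillettidia versicolor","HLC","indoor","massavasse","aggregate",0
"Coquillettidia versicolor","HLC","outdoor","massavasse","aggregate",1
"Coquillettidia versicolor","SHK","indoor","massavasse","aggregate",0
"Coquillettidia versicolor","SHK","outdoor","massavasse","aggregate",0
"Mansonia africana","HLC","indoor","massavasse","aggregate",1521
"Mansonia africana","HLC","outdoor","massavasse","aggregate",2594
"Mansonia africana","SHK","indoor","massavasse","aggregate",510
"Mansonia africana","SHK","outdoor","massavasse","aggregate",857
"Mansonia uniformis","HLC","indoor","massavasse","aggregate",11156
"Mansonia uniformis","HLC","outdoor","massavasse","aggregate",19912
"Mansonia uniformis","SHK","indoor","massavasse","aggregate",5467
"Mansonia uniformis","SHK","outdoor","massavasse","aggregate",14527
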