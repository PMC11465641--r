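synonym,compound_id
"p,p'-DDE",DDEPP
"4,4'-DDE",DDEPP
"pp-DDE",DDEPP
"p,p'-DDT",DDTPP
"4,4'-DDT",DDTPP
"p,p'-DDD",DDDPP
"4,4'-DDD",DDDPP
hexachlorobenzene,HCB
"PCB-28",PCB28
"PCB 28",PCB28
"CB-28",PCB28
"PCB-52",PCB52
"PCB-101",PCB101
"PCB-118",PCB118
"PCB-138",PCB138
"PCB-153",PCB153
"PCB 153",PCB153
"CB-153",PCB153
"2,2',4,4',5,5'-hexachlorobiphenyl",PCB153
"PCB-180",PCB180
"BDE-47",BDE47
"BDE 47",BDE47
"2,2',4,4'-tetrabromodiphenyl ether",BDE47
perfluorooctanesulfonic acid,PFOS
perfluorooctane sulfonate,PFOS
perfluorooctanoic acid,PFOA
dieldrin,DIELDRIN
"trans-nonachlor",TNONACHLOR
mirex,MIREX
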