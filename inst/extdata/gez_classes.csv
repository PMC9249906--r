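num,code,label
10,TAr,Tropical rainforest
11,TAwa,Tropical moist forest
12,TAwb,Tropical dry forest
13,TBSh,Tropical shrubland
14,TBWh,Tropical desert
15,TM,Tropical mountain system
20,SCf,Subtropical humid forest
21,SCs,Subtropical dry forest
22,SBSh,Subtropical steppe
23,SBWh,Subtropical desert
24,SM,Subtropical mountain system
30,TeDo,Temperate oceanic forest
31,TeDc,Temperate continental forest
32,TeBSk,Temperate steppe
33,TeBWk,Temperate desert
34,TeM,Temperate mountain system
40,Ba,Boreal coniferous forest
41,Bb,Boreal tundra woodland
42,BM,Boreal mountain system
50,P,Polar
90,WA,Water
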