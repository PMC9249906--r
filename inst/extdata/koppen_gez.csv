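koppen,gez
Af,TAr
Am,TAr
Am,TAwa
Aw,TAwa
Aw,TAwb
As,TAwb
BSh,TBSh
BSh,SBSh
BWh,TBWh
BWh,SBWh
BSk,SBSh
BSk,TeBSk
BWk,SBWh
BWk,TeBWk
Csa,SCs
Csb,SCs
Csb,TeDo
Cfa,SCf
Cfb,TeDo
Cfc,TeDo
Cwa,SCf
Cwa,TAwa
Cwb,TM
Cwb,SM
Cwc,TM
Dfa,TeDc
Dfb,TeDc
Dfc,Ba
Dfd,Bb
Dwa,TeDc
Dwb,TeDc
Dwc,Ba
Dwd,Bb
Dsa,TeBSk
Dsa,TeM
Dsb,TeM
Dsc,BM
ET,P
ET,BM
ET,TeM
EF,P
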