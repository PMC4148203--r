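alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy
boundary,+,root,"FSC-A,SSC-A",boundary,min=0:0,FALSE,
singlets,+,boundary,"FSC-A,FSC-H",singletGate,,FALSE,
live,-,singlets,ViViD,mindensity,,FALSE,
cd3,+,live,CD3,mindensity,,FALSE,
cd4cd8,cd4+/-cd8+/-,cd3,"CD4,CD8",mindensity,,FALSE,
IFNg,+,CD4+CD8-,IFNg,tailgate,,TRUE,PTID:VISITNO
IL2,+,CD4+CD8-,IL2,tailgate,,TRUE,PTID:VISITNO
TNFa,+,CD4+CD8-,TNFa,tailgate,,TRUE,PTID:VISITNO
GzB,+,CD4+CD8-,GzB,mindensity,adjust=2,TRUE,PTID:VISITNO
CD57,+,CD4+CD8-,CD57,mindensity,,TRUE,PTID:VISITNO
IFNg_8,IFNg+,CD4-CD8+,IFNg,tailgate,,TRUE,PTID:VISITNO
IL2_8,IL2+,CD4-CD8+,IL2,tailgate,,TRUE,PTID:VISITNO
TNFa_8,TNFa+,CD4-CD8+,TNFa,tailgate,,TRUE,PTID:VISITNO
GzB_8,GzB+,CD4-CD8+,GzB,mindensity,adjust=2,TRUE,PTID:VISITNO
CD57_8,CD57+,CD4-CD8+,CD57,mindensity,,TRUE,PTID:VISITNO
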