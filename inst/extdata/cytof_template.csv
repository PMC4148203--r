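alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy
dna,+,root,"DNA1,DNA2",dnaGate,,FALSE,
cd3,+,dna,CD3,mindensity,,FALSE,
cd8,+,cd3,CD8,mindensity,,FALSE,
mat,cd45ra+/-ccr7+/-,cd8,"CD45RA,CCR7",mindensity,,FALSE,
TNFa_1,TNFa+,CD45RA+CCR7+,TNFa,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IFNg_1,IFNg+,CD45RA+CCR7+,IFNg,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1b_1,MIP1b+,CD45RA+CCR7+,MIP1b,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1a_1,MIP1a+,CD45RA+CCR7+,MIP1a,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IL2_1,IL2+,CD45RA+CCR7+,IL2,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GMCSF_1,GMCSF+,CD45RA+CCR7+,GMCSF,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
CD107_1,CD107+,CD45RA+CCR7+,CD107,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GzB_1,GzB+,CD45RA+CCR7+,GzB,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
Perforin_1,Perforin+,CD45RA+CCR7+,Perforin,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
TNFa_2,TNFa+,CD45RA-CCR7+,TNFa,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IFNg_2,IFNg+,CD45RA-CCR7+,IFNg,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1b_2,MIP1b+,CD45RA-CCR7+,MIP1b,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1a_2,MIP1a+,CD45RA-CCR7+,MIP1a,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IL2_2,IL2+,CD45RA-CCR7+,IL2,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GMCSF_2,GMCSF+,CD45RA-CCR7+,GMCSF,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
CD107_2,CD107+,CD45RA-CCR7+,CD107,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GzB_2,GzB+,CD45RA-CCR7+,GzB,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
Perforin_2,Perforin+,CD45RA-CCR7+,Perforin,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
TNFa_3,TNFa+,CD45RA-CCR7-,TNFa,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IFNg_3,IFNg+,CD45RA-CCR7-,IFNg,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1b_3,MIP1b+,CD45RA-CCR7-,MIP1b,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1a_3,MIP1a+,CD45RA-CCR7-,MIP1a,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IL2_3,IL2+,CD45RA-CCR7-,IL2,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GMCSF_3,GMCSF+,CD45RA-CCR7-,GMCSF,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
CD107_3,CD107+,CD45RA-CCR7-,CD107,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GzB_3,GzB+,CD45RA-CCR7-,GzB,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
Perforin_3,Perforin+,CD45RA-CCR7-,Perforin,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
TNFa_4,TNFa+,CD45RA+CCR7-,TNFa,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IFNg_4,IFNg+,CD45RA+CCR7-,IFNg,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1b_4,MIP1b+,CD45RA+CCR7-,MIP1b,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
MIP1a_4,MIP1a+,CD45RA+CCR7-,MIP1a,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
IL2_4,IL2+,CD45RA+CCR7-,IL2,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GMCSF_4,GMCSF+,CD45RA+CCR7-,GMCSF,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
CD107_4,CD107+,CD45RA+CCR7-,CD107,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
GzB_4,GzB+,CD45RA+CCR7-,GzB,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
Perforin_4,Perforin+,CD45RA+CCR7-,Perforin,refGate,"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99",FALSE,
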