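sample,rna,condition,level_imp_per_1e6_amp,sd,n,denominator
fluc_0.1mM,FLuc,0.1 mM ITP,427,151,3,9379
fluc_1mM,FLuc,1 mM ITP,4055,1285,3,986
fluc_10mM,FLuc,10 mM ITP,21649,3369,3,185
rluc_0.1mM,RLuc,0.1 mM ITP,1038,289,3,3856
rluc_1mM,RLuc,1 mM ITP,8112,1039,3,493
rluc_10mM,RLuc,10 mM ITP,48355,7666,3,82
mouse_heart_null,total RNA,Itpa-null embryonic heart,10382,2008,3,385
h9c2_null,total RNA,Itpa-null H9c2 cells,442,25,3,9037
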