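panel,design_id,antibody,mutations,disruptive,disrupted_ab
single,TZ47-Ag1,TZ47,F47Y;N49Q;W98E,FALSE,
single,TZ47-Ag2,TZ47,F184D;I188Q;V225T,FALSE,
single,TZ47-Ag3,TZ47,T71K;K74E;V76H,FALSE,
single,TZ47-Ag4,TZ47,M154E;N157G;S217H,TRUE,TZ47
single,PB-Ag1,PB11,M30V;Q132V;Q136L,FALSE,
single,PB-Ag2,PB11,F51H;Y52D;R99G,TRUE,PB11
single,PB-Ag3,PB11,A88T;F89T;G111R,FALSE,
single,PB-Ag4,PB11,T176K;V194I;R231E,FALSE,
single,PB-Ag5,PB11,N216K;S217A;Q219V,FALSE,
multi,MULTI-1,both,N57D;D84N;W98E,TRUE,PB11
multi,MULTI-2,both,F66Y;T71K;F72D,FALSE,
multi,MULTI-3,both,V78L;F89T;G111R,FALSE,
multi,MULTI-4,both,M154E;N157E;N216K,TRUE,TZ47
multi,MULTI-5,both,A172H;R231E;A233E,FALSE,
multi,MULTI-6,both,T176K;R231E;H236S,FALSE,
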