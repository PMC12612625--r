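site,variety,tree,LMA,LDMC
subhumid,Picholine marocaine,t1,250.1,455.2
subhumid,Picholine marocaine,t2,261.4,449.8
subhumid,Lucques,t1,232.0,430.5
subhumid,Lucques,t2,228.7,441.1
subhumid,Aglandau,t1,270.3,460.9
subhumid,Aglandau,t2,265.8,452.3
semiarid,Picholine marocaine,t1,301.6,495.0
semiarid,Picholine marocaine,t2,296.2,488.4
semiarid,Haouzia,t1,288.9,470.2
semiarid,Haouzia,t2,280.5,476.8
semiarid,Menara,t1,310.0,501.3
semiarid,Menara,t2,305.4,NA
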