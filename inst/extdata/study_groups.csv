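farm,group,cat1,cat2,cat3,cat4,cat5,cat6
A,1,4,0,0,0,0,0
A,2,3,1,0,0,0,0
B,3,7,0,0,0,0,0
C,4,1,0,0,3,0,0
D,5,0,0,0,1,5,0
D,6,0,0,0,1,5,0
E,7,1,0,1,1,0,0
F,8,1,0,3,0,0,0
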