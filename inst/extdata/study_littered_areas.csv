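group,T0,T0.5,T1,T1.5
1,0.0,8.0,16.0,24.0
2,0.0,8.3,16.5,24.8
3,0.0,14.0,28.0,42.0
4,0.0,11.0,22.0,33.0
5,0.0,21.8,43.5,65.3
6,0.0,21.8,43.5,65.3
7,0.0,7.8,15.5,23.3
8,0.0,10.2,20.5,30.8
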