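H,p_c,mcse,N,T_gen,n_reps,tol
0,0.4630859375,0.00251655312562798,1000,10000,100,0.005
1,0.6529296875,0.00252034632793441,1000,10000,100,0.005
2,0.7443359375,0.00251258020395961,1000,10000,100,0.005
3,0.7970703125,0.00251552200638448,1000,10000,100,0.005
4,0.8322265625,0.00251552200638448,1000,10000,100,0.005
5,0.8568359375,0.00251655312562797,1000,10000,100,0.005
6,0.8779296875,0.00251372886540259,1000,10000,100,0.005
7,0.8919921875,0.00251125990508847,1000,10000,100,0.005
8,0.9025390625,0.00250698414381547,1000,10000,100,0.005
9,0.9130859375,0.0025236475191,1000,10000,100,0.005
10,0.9201171875,0.00250988242167481,1000,10000,100,0.005
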