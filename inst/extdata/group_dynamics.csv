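intervention,sex,test_kind,week,G0,A,alpha,T_period,phi
STD,F,GTT,0,106,85,0.9,3,-0.15
STD,M,GTT,0,104,85,0.9,3,-0.15
HFHSD,F,GTT,0,106,85,0.9,3,-0.15
HFHSD,M,GTT,0,104,85,0.9,3,-0.15
HFHSD+M,F,GTT,0,106,85,0.9,3,-0.15
HFHSD+M,M,GTT,0,104,85,0.9,3,-0.15
HFHSD+L,F,GTT,0,106,85,0.9,3,-0.15
HFHSD+L,M,GTT,0,104,85,0.9,3,-0.15
STD,F,GTT,5,107.6667,83.6111,0.9139,3,-0.1361
STD,M,GTT,5,105.1111,82.2222,0.9556,2.9444,-0.1417
HFHSD,F,GTT,5,112.6667,105.8333,0.7472,3.8333,-0.1222
HFHSD,M,GTT,5,108.4444,91.9444,0.7889,3.5556,-0.1222
HFHSD+M,F,GTT,5,112.6667,105.8333,0.7472,3.8333,-0.1222
HFHSD+M,M,GTT,5,108.4444,91.9444,0.7889,3.5556,-0.1222
HFHSD+L,F,GTT,5,112.6667,105.8333,0.7472,3.8333,-0.1222
HFHSD+L,M,GTT,5,108.4444,91.9444,0.7889,3.5556,-0.1222
STD,F,GTT,12,111,80.8333,0.9417,3,-0.1083
STD,M,GTT,12,107.3333,76.6667,1.0667,2.8333,-0.125
HFHSD,F,GTT,12,126,147.5,0.4417,5.5,-0.0667
HFHSD,M,GTT,12,117.3333,105.8333,0.5667,4.6667,-0.0667
HFHSD+M,F,GTT,12,124,152.5,0.4417,5.6,-0.0667
HFHSD+M,M,GTT,12,115.3333,100.8333,0.5667,4.7667,-0.0667
HFHSD+L,F,GTT,12,128.5,160,0.4167,6,-0.0517
HFHSD+L,M,GTT,12,121.3333,138.3333,0.5067,5.1667,-0.0667
STD,F,GTT,18,112,80,0.95,3,-0.1
STD,M,GTT,18,108,75,1.1,2.8,-0.12
HFHSD,F,GTT,18,130,160,0.35,6,-0.05
HFHSD,M,GTT,18,120,110,0.5,5,-0.05
HFHSD+M,F,GTT,18,126,170,0.35,6.2,-0.05
HFHSD+M,M,GTT,18,116,100,0.5,5.2,-0.05
HFHSD+L,F,GTT,18,135,185,0.3,7,-0.02
HFHSD+L,M,GTT,18,128,175,0.38,6,-0.05
STD,M,ITT,18,85,40,0.55,2.5,2.5
STD,F,ITT,18,88,40,0.5,2.6,2.5
HFHSD,M,ITT,18,98,42,0.4,3,2.5
HFHSD,F,ITT,18,105,44,0.36,3.1,2.5
HFHSD+M,M,ITT,18,95,42,0.42,2.9,2.5
HFHSD+M,F,ITT,18,102,44,0.38,3,2.5
HFHSD+L,M,ITT,18,100,44,0.4,3,2.5
HFHSD+L,F,ITT,18,115,45,0.35,3.2,2.5
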