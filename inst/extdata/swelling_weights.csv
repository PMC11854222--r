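t_min,y,sd
0,0.00035,0.00001
60,0.00075,0.00002
180,0.00080,0.00007
300,0.00108,0.00002
1440,0.00160,0.00002
2880,0.00162,0.00002
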