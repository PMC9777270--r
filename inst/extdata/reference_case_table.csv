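t,V,n,crude,linear,simulated
0,33726,1,0.01,0.01,0.01
10,24264,0.785,0.0089,0.0087,0.0096
50,41447,1.229,0.0111,0.0112,0.0102
100,71778,2.128,0.0146,0.0153,0.0116
150,118172,3.504,0.0187,0.0202,0.014
200,184578,5.473,0.0234,0.0259,0.0176
250,273510,8.110,0.0285,0.0324,0.0227
300,384156,11.39,0.0337,0.0392,0.0291
350,510781,15.14,0.0389,0.0459,0.0367
400,642925,19.06,0.0437,0.0523,0.0451
450,768233,22.78,0.0477,0.0578,0.0535
500,876630,25.99,0.0510,0.0622,0.0614
550,963109,28.56,0.0534,0.0656,0.0684
600,1027711,30.47,0.0552,0.0680,0.0743
650,1073622,31.83,0.0564,0.0697,0.0793
700,1105104,32.77,0.0572,0.0709,0.0834
750,1126165,33.39,0.0578,0.0716,0.0868
800,1140022,33.80,0.0581,0.0721,0.0897
850,1149042,34.07,0.0584,0.0724,0.0922
900,1154872,34.24,0.0585,0.0726,0.0944
950,1158622,34.35,0.0586,0.0728,0.0963
1000,1160215,34.40,0.0587,0.0728,0.098
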