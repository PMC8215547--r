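cell,gsyn_1e3_uS,tau_ms,delay_ms
1,0.72,4.50,1.80
2,0.59,5.70,2.00
3,0.34,4.55,2.00
4,0.73,7.80,2.00
5,0.69,5.75,2.00
6,0.63,6.96,1.30
7,1.15,5.95,2.00
8,0.21,6.00,2.00
9,1.17,4.40,1.40
10,2.28,4.75,1.30
11,0.59,4.90,2.00
12,0.41,6.99,2.00
mean,0.79,5.69,1.82
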