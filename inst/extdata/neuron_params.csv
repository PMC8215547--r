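cell,cm_uF_cm2,E_L_mV,g_L_1e3_S_cm2,g_Na_1e2_S_cm2,g_DR_1e2_S_cm2,g_AHP_1e2_S_cm2,g_Ca_1e2_S_cm2,g_C_1e2_S_cm2
1,10,-45,1.10,8,2,1,0.8,2
2,8,-40,0.85,6,2,0.9,0.8,2
3,10,-45,1.48,15,0.5,0.1,0.8,2
4,15,-35,1.15,29,2,0.45,0.8,2.5
5,15,-45,1.48,25,1,0.1,0.8,10
6,10,-56,2.10,9,9.9,3,0.8,20
7,8,-50,0.8,7,2,0.5,0.8,2
8,10,-60,1.10,11,12,0.5,0.8,2
9,8,-60,0.70,8,6,12,0.8,10
mean,10.44,-48.44,1.20,13.11,4.16,2.06,0.80,5.83
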