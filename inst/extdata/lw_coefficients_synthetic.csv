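species,lw_a,lw_b
Epinephelus marginatus,0.0112,3.05
Dentex dentex,0.0135,2.96
Diplodus sargus,0.0151,3.02
Coris julis,0.0077,3.08
Chromis chromis,0.0132,3.01
Sarpa salpa,0.0103,3.06
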