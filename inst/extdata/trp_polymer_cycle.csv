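complex,dG_bind_gas,dGsolv_X,dGsolv_L,dGsolv_complex,published_ddG_solv,published_dG_aq
Trp-dextran 40,-4.0,-16.3,-87.3,-101.3,2.3,-1.7
Trp-ficoll 70,1.0,-16.3,-124.3,-140.0,1.4,2.4
Trp-PVP 40,-6.3,-16.3,-69.3,-79.6,6.5,0.2
Trp-PEG 8,7.7,-16.3,-21.5,-36.9,1.1,8.8
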