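complex,dG_bind_gas,dGsolv_X,dGsolv_L,dGsolv_complex,published_ddG_solv,published_dG_aq
indole-dextrose,2.1,-6.2,-25.8,-23.4,8.6,10.7
indole-sucrose,1.7,-6.2,-37.0,-38.2,5.0,6.7
indole-1-ethyl-2-pyrrolidone,1.5,-6.2,-7.8,-8.7,5.3,6.8
indole-ethylene glycol,-1.0,-6.2,-11.4,-9.7,7.9,6.9
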