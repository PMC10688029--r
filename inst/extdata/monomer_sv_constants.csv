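crowder,K_SV_25,r2_25,K_SV_50,r2_50
dextrose,0.0415,0.90,-0.038,0.74
sucrose,0.444,0.96,0.241,1.0
ethylene glycol,-0.0325,0.97,-0.040,0.94
1-ethyl-2-pyrrolidone,0.254,0.92,0.138,0.84
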