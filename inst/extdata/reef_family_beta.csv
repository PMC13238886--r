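family,ocean,n_species,beta_jac,beta_jtu,beta_jne
Acanthuridae,Caribbean Sea,5,0.400,0.000,0.400
Acanthuridae,Western Indian Ocean,42,0.410,0.207,0.203
Labridae,Caribbean Sea,32,0.406,0.000,0.406
Labridae,Western Indian Ocean,93,0.437,0.270,0.167
Mullidae,Caribbean Sea,5,0.200,0.000,0.200
Mullidae,Western Indian Ocean,17,0.286,0.118,0.168
Pomacentridae,Caribbean Sea,21,0.284,0.111,0.172
Pomacentridae,Western Indian Ocean,71,0.487,0.185,0.302
Tetraodontidae,Caribbean Sea,12,0.429,0.333,0.095
Tetraodontidae,Western Indian Ocean,22,0.363,0.038,0.325
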