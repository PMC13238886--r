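species,family,ocean,n_individuals,beta_gd
Acanthurus tractus,Acanthuridae,Caribbean Sea,42,0.0350
Ctenochaetus striatus,Acanthuridae,Western Indian Ocean,69,0.0106
Halichoeres garnoti,Labridae,Caribbean Sea,28,0.0149
Gomphosus caeruleus,Labridae,Western Indian Ocean,44,0.0172
Halichoeres hortulanus,Labridae,Western Indian Ocean,46,0.0202
Hemigymnus fasciatus,Labridae,Western Indian Ocean,44,0.0727
Mulloidichthys martinicus,Mullidae,Caribbean Sea,53,-0.0100
Parupeneus macronemus,Mullidae,Western Indian Ocean,56,0.0354
Azurina cyanea,Pomacentridae,Caribbean Sea,54,0.0147
Azurina multilineata,Pomacentridae,Caribbean Sea,51,0.0370
Stegastes partitus,Pomacentridae,Caribbean Sea,46,0.0216
Chromis atripectoralis,Pomacentridae,Western Indian Ocean,35,0.0654
Chromis ternatensis,Pomacentridae,Western Indian Ocean,49,0.0435
Chromis weberi,Pomacentridae,Western Indian Ocean,45,0.0631
Dascyllus aruanus,Pomacentridae,Western Indian Ocean,39,0.0522
Dascyllus carneus,Pomacentridae,Western Indian Ocean,55,0.0232
Dascyllus trimaculatus,Pomacentridae,Western Indian Ocean,40,0.0231
Canthigaster rostrata,Tetraodontidae,Caribbean Sea,57,0.0116
Canthigaster valentini,Tetraodontidae,Western Indian Ocean,44,0.0284
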