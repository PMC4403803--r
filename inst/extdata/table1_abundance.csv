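species,family,status,total_abundance,forest_plots,grassland_plots
Cymbopogon plurinodis,Poaceae,indigenous,491,0,6
Digitaria eriantha,Poaceae,indigenous,395,0,6
Oplismenus hirtellus,Poaceae,indigenous,251,8,0
Cyperus albostriatus,Cyperaceae,indigenous,249,6,0
Gerbera piloselloides,Asteraceae,indigenous,189,0,9
Chromolaena odorata,Asteraceae,alien,88,9,3
Sonchus oleraceus,Asteraceae,alien,43,0,7
Sorghum halepense,Poaceae,alien,27,2,0
Tagetes minuta,Asteraceae,alien,25,0,1
Melia azedarach,Meliaceae,alien,17,1,5
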