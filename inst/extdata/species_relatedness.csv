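species,related_species
Dermochelys coriacea,Caretta caretta
Dermochelys coriacea,Chelonia mydas
Chelydra serpentina,Malaclemys terrapin
Nerodia sipedon,Enhydris chinensis
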