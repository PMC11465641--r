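species,tissue,water_fraction,reference
Chelonia mydas,whole_egg,0.667,synthetic stand-in
Chelonia mydas,plasma,0.92,synthetic stand-in
Caretta caretta,whole_egg,0.667,synthetic stand-in
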