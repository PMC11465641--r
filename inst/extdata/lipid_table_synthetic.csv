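species,tissue,lipid_fraction,source,reference
Malaclemys terrapin,fat,0.60,same_species_literature,synthetic stand-in
Malaclemys terrapin,liver,0.05,same_species_literature,synthetic stand-in
Malaclemys terrapin,whole_blood,0.005,same_species_literature,synthetic stand-in
Malaclemys terrapin,muscle,0.02,same_species_literature,synthetic stand-in
Malaclemys terrapin,whole_egg,0.08,same_species_literature,synthetic stand-in
Enhydris chinensis,liver,0.05,same_species_literature,synthetic stand-in
Enhydris chinensis,whole_blood,0.005,same_species_literature,synthetic stand-in
Enhydris chinensis,plasma,0.006,same_species_literature,synthetic stand-in
Enhydris chinensis,muscle,0.02,same_species_literature,synthetic stand-in
Enhydris chinensis,kidney,0.04,same_species_literature,synthetic stand-in
Enhydris chinensis,fat,0.60,same_species_literature,synthetic stand-in
Enhydris chinensis,whole_egg,0.08,same_species_literature,synthetic stand-in
Chelonia mydas,plasma,0.006,same_species_literature,synthetic stand-in
Chelonia mydas,whole_egg,0.08,same_species_literature,synthetic stand-in
Caretta caretta,whole_blood,0.005,same_species_literature,synthetic stand-in
Caretta caretta,yolk,0.22,same_species_literature,synthetic stand-in
Caretta caretta,whole_egg,0.08,same_species_literature,synthetic stand-in
Alligator mississippiensis,liver,0.05,same_species_literature,synthetic stand-in
Alligator mississippiensis,yolk,0.22,same_species_literature,synthetic stand-in
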