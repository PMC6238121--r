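site,criteria,species,stages,min_pairs,max_pairs,colony_size_pairs
Admiralty Bay,A4iii,adelie,incubation;brood;creche,1406,7032,7032
Admiralty Bay,A4iii,chinstrap,brood,190,950,950
Admiralty Bay,A4iii,gentoo,brood;creche,947,4736,4736
Monroe,A4ii;A4iii,chinstrap,incubation;brood;creche,6667,33333,33333
Powell,A4ii;A4iii,adelie,brood,9988,49938,49938
Powell,A4ii;A4iii,chinstrap,incubation;brood,11043,55213,55213
Powell,A4ii;A4iii,adelie,brood,3667,17600,18333
Signy,A4iii,chinstrap,incubation;brood,3906,15190,19530
Signy,A4iii,gentoo,incubation,263,1315,1315
Hope Bay,A4iii,adelie,brood,24770,123850,123850
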