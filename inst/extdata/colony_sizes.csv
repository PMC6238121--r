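species,site,colony,stage,device,n_birds,used_to_test,colony_size_pairs
adelie,South Shetland,Admiralty Bay,brood,PTT,14,0,7032
adelie,South Shetland,Admiralty Bay,creche,PTT,41,0,7032
adelie,South Shetland,Admiralty Bay,incubation,PTT,22,0,7032
adelie,South Orkney,Powell Island,brood,PTT,10,0,49938
adelie,South Orkney,Signy Island (Gourlay),brood,GPS,25,0,18333
adelie,South Orkney,Signy Island (Gourlay),brood,PTT,24,0,18333
adelie,South Orkney,Signy Island (N Point),brood,PTT,9,0,18333
adelie,Antarctic Peninsula,Hope Bay,brood,PTT,10,0,123850
chinstrap,South Shetland,Admiralty Bay,brood,PTT,32,0,950
chinstrap,South Shetland,King George Island,brood,GPS,48,0,3158
chinstrap,South Orkney,Laurie,brood,GPS,21,1,2439
chinstrap,South Orkney,Laurie,incubation,GPS,34,1,2439
chinstrap,South Orkney,Monroe,brood,GPS,28,1,33333
chinstrap,South Orkney,Monroe,incubation,GPS,13,1,33333
chinstrap,South Orkney,Monroe,creche,GPS,12,1,33333
chinstrap,South Orkney,Powell,brood,GPS,34,1,55213
chinstrap,South Orkney,Powell,incubation,GPS,13,1,55213
chinstrap,South Orkney,Signy Island (2013),incubation,GPS,9,1,19530
chinstrap,South Orkney,Signy Island (2015),brood,GPS,13,1,19530
chinstrap,South Orkney,Signy Island (2015),incubation,GPS,9,1,19530
gentoo,South Shetland,Admiralty Bay,brood,PTT,23,0,4736
gentoo,South Shetland,Admiralty Bay,creche,PTT,37,0,4736
gentoo,South Shetland,King George Island,brood,GPS,42,0,2378
gentoo,South Orkney,Signy Island (North Point),incubation,GPS,6,0,1315
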