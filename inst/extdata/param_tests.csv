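colony,stage,n_birds,mean_max_distance_km,h_ars_km,best_h_km,best_ud_percent,area_km2,inclusion
Laurie,incubation,34,34.06,4.29,7,70,759,72.26
Monroe,incubation,13,126.72,17.43,8,80,5343,60.95
Powell,incubation,13,121.54,17.55,9,70,3669,62.67
Signy2013,incubation,9,132.89,7.34,7,80,9340,78.54
Signy2015,incubation,9,144.96,11.20,7,80,8932,67.98
Laurie,brood,21,22.05,3.54,7,55,641,88.86
Monroe,brood,28,19.58,1.56,7,55,1056,83.98
Powell,brood,34,32.73,2.603,6,55,694,83.92
Signy2015,brood,13,72.00,11.58,7,70,2394,72.71
Monroe,creche,12,54.67,8.22,8,60,1632,76.76
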