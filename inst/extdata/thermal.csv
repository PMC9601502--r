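species,actual_pct,treatment_min,measured_pct,measured_sd,deviation_pct
pork,10,5,9.5,0.36,-4.97
pork,10,10,8.96,0.33,-10.36
pork,10,20,8.39,0.1,-16.1
pork,50,5,51.63,0.62,3.26
pork,50,10,53.48,0.77,6.97
pork,50,20,53.99,0.17,7.99
chicken,10,5,9.22,0.31,-7.77
chicken,10,10,9,0.4,-10.03
chicken,10,20,8.49,0.04,-15.1
chicken,50,5,51.87,0.48,3.75
chicken,50,10,52.79,0.99,5.59
chicken,50,20,42.77,5.26,-14.46
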