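sample_id,species,declared_pct,measured_pct
Beef roll,pork,0,0
Beef roll,chicken,0,0
Beef ball_1,pork,0,0
Beef ball_1,chicken,0,0
Beef ball_2,pork,19,31.67
Beef ball_2,chicken,0,0
Beef kebabs_1,pork,0,0
Beef kebabs_1,chicken,0,0
Beef kebabs_2,pork,0,0
Beef kebabs_2,chicken,0,0
Beefsteak,pork,0,0
Beefsteak,chicken,0,0
Minced beef,pork,0,0
Minced beef,chicken,0,65.9
Beef stick,pork,0,0
Beef stick,chicken,0,0
Beef slice,pork,0,0
Beef slice,chicken,0,0
Veal sausage,pork,0,0
Veal sausage,chicken,0,0
Beef sausage,pork,0,0
Beef sausage,chicken,49.4,50.25
Canned beef,pork,0,0
Canned beef,chicken,0,0
Dried beef jerky,pork,NA,17.47
Dried beef jerky,chicken,0,0
Dried beef floss,pork,0,0
Dried beef floss,chicken,0,0
Cured beef,pork,0,0
Cured beef,chicken,0,0
Bresaola,pork,0,0
Bresaola,chicken,0,0
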