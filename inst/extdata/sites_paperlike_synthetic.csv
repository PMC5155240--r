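"site_id","vegetation_type","region","biome_label","area","ndep_profile","temp_mean","temp_amp","precip_ann"
"USTF-1",5,"USA","temperate_forest",1e+10,"us_temperate_forest",9.22708214077378,10,1078.67833958348
"EUTF-1",5,"Europe","temperate_forest",1e+10,"europe_forest",7.52230437863298,9,857.003808199866
"ASGR-1",10,"China","grassland",1e+10,"asia_grassland",11.603732157909,11,644.448603249108
"BOBG-1",6,"Other","boreal_forest",1e+10,"background",-0.355210086878531,16,479.013413853628
"USTF-2",5,"USA","temperate_forest",1e+10,"us_temperate_forest",9.45779726004577,10,1086.50631397614
"EUTF-2",5,"Europe","temperate_forest",1e+10,"europe_forest",7.63719378895031,9,858.628092221862
"ASGR-2",10,"China","grassland",1e+10,"asia_grassland",11.896976707097,11,659.633780930274
"BOBG-2",6,"Other","boreal_forest",1e+10,"background",-0.653018351094315,16,491.459991271971
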