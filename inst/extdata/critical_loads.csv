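"vegetation_type","name","usa","china","europe","other","provenance_other"
1,"tropical evergreen forest",0.9,5.6,NA,3.25,"filled"
2,"tropical deciduous forest",0.9,5.6,NA,3.25,"filled"
3,"temperate evergreen broadleaf forest",0.9,2.25,1.5,1.55,"filled"
4,"temperate evergreen conifer forest",0.9,2.25,1.5,1.55,"filled"
5,"temperate deciduous forest",0.9,2.25,1.5,1.55,"filled"
6,"boreal evergreen forest",0.57,1.25,1.25,1.02,"filled"
7,"boreal deciduous forest",0.57,1.25,1.25,1.02,"filled"
8,"mixed forest",0.8,2.9,1.4,1.7,"filled"
9,"savanna",NA,5,NA,5,"filled"
10,"grassland",NA,1.25,1.45,1.35,"filled"
11,"dense shrubland",0.47,0.92,NA,0.69,"published"
12,"open shrubland",0.47,0.92,NA,0.69,"published"
13,"tundra",0.2,0.75,0.4,0.45,"filled"
14,"desert",0,1,0,1,"published"
15,"polar desert/rock/ice",0,1,0,1,"published"
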