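subject,species,experiment,trial,entered,removed,first_touch,offered,note
Manda,Pan troglodytes,exp2,1,1,metal;wood;jute,UNKNOWN,UNKNOWN,the one non-target first touch is not identified by trial
Manda,Pan troglodytes,exp2,2,1,metal;rope;wood,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,3,1,metal;rope,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,4,1,metal;rope,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,5,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,6,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,7,1,metal;wood,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,8,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,9,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,10,1,metal;rope,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,11,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Manda,Pan troglodytes,exp2,12,1,metal,metal,UNKNOWN,exchange outcomes recorded in aggregate only
Maria-Magdalena,Pan troglodytes,exp2,1,1,metal;rope;wood;jute,UNKNOWN,metal,first touch identified only in aggregate (6 of 12 trials)
Maria-Magdalena,Pan troglodytes,exp2,2,1,wood;jute,UNKNOWN,NONE,first touch identified only in aggregate (6 of 12 trials)
Maria-Magdalena,Pan troglodytes,exp2,3,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,4,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,5,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,6,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,7,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,8,1,rope;wood,UNKNOWN,NONE,first touch identified only in aggregate (6 of 12 trials)
Maria-Magdalena,Pan troglodytes,exp2,9,1,metal,metal,metal,
Maria-Magdalena,Pan troglodytes,exp2,10,1,rope;wood,UNKNOWN,NONE,first touch identified only in aggregate (6 of 12 trials)
Maria-Magdalena,Pan troglodytes,exp2,11,1,rope,UNKNOWN,NONE,first touch identified only in aggregate (6 of 12 trials)
Maria-Magdalena,Pan troglodytes,exp2,12,1,rope,UNKNOWN,NONE,first touch identified only in aggregate (6 of 12 trials)
Naong,Pongo abelii,exp2,1,1,metal,metal,metal,
Naong,Pongo abelii,exp2,2,1,metal,metal,metal,
Naong,Pongo abelii,exp2,3,1,metal,metal,metal,
Naong,Pongo abelii,exp2,4,0,,NONE,NONE,
Naong,Pongo abelii,exp2,5,0,,NONE,NONE,
Naong,Pongo abelii,exp2,6,0,,NONE,NONE,
Naong,Pongo abelii,exp2,7,0,,NONE,NONE,
Naong,Pongo abelii,exp2,8,1,metal,metal,metal,
Naong,Pongo abelii,exp2,9,1,metal,metal,metal,
Naong,Pongo abelii,exp2,10,1,metal,metal,metal,
Naong,Pongo abelii,exp2,11,1,rope;wood,metal,wood,touched the target first but displaced it out of reach
Naong,Pongo abelii,exp2,12,1,metal,metal,metal,
Dunja,Pongo abelii,exp2,1,0,,NONE,NONE,foreign: faeces (trial identity not recorded)
Dunja,Pongo abelii,exp2,2,0,,NONE,NONE,foreign: sponge (trial identity not recorded)
Dunja,Pongo abelii,exp2,3,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,4,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,5,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,6,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,7,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,8,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,9,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,10,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,11,0,,NONE,NONE,
Dunja,Pongo abelii,exp2,12,0,,NONE,NONE,
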