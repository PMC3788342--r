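subject,species,experiment,trial,selected,arrived,offered,note
Manda,Pan troglodytes,preference,1,wood,0,NONE,
Manda,Pan troglodytes,preference,2,wood,0,NONE,
Manda,Pan troglodytes,preference,3,wood,0,NONE,
Manda,Pan troglodytes,preference,4,wood,0,NONE,
Manda,Pan troglodytes,preference,5,wood,0,NONE,
Manda,Pan troglodytes,preference,6,wood,0,NONE,
Manda,Pan troglodytes,preference,7,wood,0,NONE,
Manda,Pan troglodytes,preference,8,wood,0,NONE,
Manda,Pan troglodytes,preference,9,wood,0,NONE,
Manda,Pan troglodytes,preference,10,wood,0,NONE,
Manda,Pan troglodytes,preference,11,wood,0,NONE,
Manda,Pan troglodytes,preference,12,wood,0,NONE,
Manda,Pan troglodytes,preference,13,rope,0,NONE,
Manda,Pan troglodytes,preference,14,rope,0,NONE,
Manda,Pan troglodytes,preference,15,jute,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,1,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,2,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,3,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,4,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,5,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,6,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,7,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,8,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,9,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,10,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,11,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,12,wood,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,13,rope,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,14,rope,0,NONE,
Maria-Magdalena,Pan troglodytes,preference,15,REFUSED,0,NONE,
Naong,Pongo abelii,preference,1,rope,0,NONE,
Naong,Pongo abelii,preference,2,rope,0,NONE,
Naong,Pongo abelii,preference,3,rope,0,NONE,
Naong,Pongo abelii,preference,4,wood,0,NONE,
Naong,Pongo abelii,preference,5,wood,0,NONE,
Naong,Pongo abelii,preference,6,wood,0,NONE,
Naong,Pongo abelii,preference,7,wood,0,NONE,
Naong,Pongo abelii,preference,8,jute,0,NONE,
Naong,Pongo abelii,preference,9,metal,0,NONE,
Naong,Pongo abelii,preference,10,metal,0,NONE,
Naong,Pongo abelii,preference,11,metal,0,NONE,
Naong,Pongo abelii,preference,12,REFUSED,0,NONE,
Naong,Pongo abelii,preference,13,REFUSED,0,NONE,
Naong,Pongo abelii,preference,14,REFUSED,0,NONE,
Naong,Pongo abelii,preference,15,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,1,wood,0,NONE,
Dunja,Pongo abelii,preference,2,wood,0,NONE,
Dunja,Pongo abelii,preference,3,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,4,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,5,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,6,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,7,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,8,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,9,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,10,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,11,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,12,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,13,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,14,REFUSED,0,NONE,
Dunja,Pongo abelii,preference,15,REFUSED,0,NONE,
Manda,Pan troglodytes,exp1,1,UNKNOWN,0,NONE,non-target selection; item identity not recorded
Manda,Pan troglodytes,exp1,2,UNKNOWN,0,NONE,non-target selection; item identity not recorded
Manda,Pan troglodytes,exp1,3,UNKNOWN,0,NONE,non-target selection; item identity not recorded
Manda,Pan troglodytes,exp1,4,metal,1,metal,
Manda,Pan troglodytes,exp1,5,UNKNOWN,0,NONE,non-target selection; item identity not recorded
Manda,Pan troglodytes,exp1,6,metal,1,metal,
Manda,Pan troglodytes,exp1,7,metal,1,metal,
Manda,Pan troglodytes,exp1,8,metal,1,metal,
Manda,Pan troglodytes,exp1,9,metal,1,metal,
Manda,Pan troglodytes,exp1,10,metal,1,metal,
Manda,Pan troglodytes,exp1,11,metal,1,metal,
Manda,Pan troglodytes,exp1,12,metal,1,metal,
Manda,Pan troglodytes,exp1,13,metal,1,metal,
Naong,Pongo abelii,exp1,1,metal,1,metal,
Naong,Pongo abelii,exp1,2,metal,1,UNKNOWN,did not bring the target to the exchange
Naong,Pongo abelii,exp1,3,metal,1,metal,
Naong,Pongo abelii,exp1,4,metal,1,metal,
Naong,Pongo abelii,exp1,5,metal,1,metal,
Naong,Pongo abelii,exp1,6,metal,1,metal,
Naong,Pongo abelii,exp1,7,metal,1,metal,
Naong,Pongo abelii,exp1,8,metal,1,metal,
Naong,Pongo abelii,exp1,9,metal,1,metal,
Naong,Pongo abelii,exp1,10,metal,1,metal,
Naong,Pongo abelii,exp1,11,metal,1,metal,
Naong,Pongo abelii,exp1,12,metal,1,metal,
Naong,Pongo abelii,exp1,13,REFUSED,0,NONE,
Dunja,Pongo abelii,exp1,1,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,2,REFUSED,0,NONE,
Dunja,Pongo abelii,exp1,3,UNKNOWN,1,NONE,"foreign: enclosure material (stick, bark, or pine needles)"
Dunja,Pongo abelii,exp1,4,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,5,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,6,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,7,metal,1,NONE,"foreign: enclosure material (stick, bark, or pine needles)"
Dunja,Pongo abelii,exp1,8,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,9,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,10,metal,1,NONE,"foreign: enclosure material (stick, bark, or pine needles)"
Dunja,Pongo abelii,exp1,11,UNKNOWN,1,NONE,unclear selection; foreign: enclosure material offered
Dunja,Pongo abelii,exp1,12,metal,0,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,13,metal,1,NONE,carried item taken by the male in the enclosure
Dunja,Pongo abelii,exp1,14,metal,0,NONE,carried item taken by the male in the enclosure
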