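crop_code,crop_class,gmin,gmax,ktmp,tmin,topmin,topmax,tmax,rmin,ropmin,ropmax,rmax,phmin,phopmin,phopmax,phmax,has_mapspam
maize,Cereals,90,140,0,10,18,33,40,400,600,1200,1800,4.5,5.5,7,8.5,TRUE
pmillet,Cereals,70,110,4,12,25,35,42,200,400,900,1500,4.5,5.5,7.5,8.5,TRUE
fmillet,Cereals,90,130,4,12,22,30,38,300,500,1100,1700,4.5,5.5,7.5,8.3,TRUE
sorghum,Cereals,90,140,2,10,24,35,42,250,450,1000,1600,4.3,5.5,7.5,8.7,TRUE
rice,Cereals,90,150,5,15,22,32,38,600,1000,2000,3000,4.5,5.5,7,8,TRUE
wheat,Cereals,100,150,-4,5,15,23,30,300,500,900,1600,5,6,7.5,8.5,TRUE
teff,Cereals,60,120,2,10,16,27,35,300,450,1100,2000,5,6,7,8,FALSE
fonio,Cereals,70,120,5,15,22,30,38,400,700,1500,2500,4.5,5.5,7,8,FALSE
cowpea,Pulses,70,120,4,12,20,32,38,300,500,1100,1800,4.5,5.5,7.5,8.5,TRUE
soybean,Pulses,90,140,0,10,20,30,38,400,600,1300,1800,4.5,5.5,7,8.4,TRUE
bambnut,Pulses,100,150,4,14,20,30,38,450,750,1400,2200,4.3,5,6.5,7.5,FALSE
peanut,Pulses,90,140,2,12,22,30,40,350,550,1200,1800,4.3,5.3,6.6,8,TRUE
commbean,Pulses,70,120,0,10,16,26,32,300,500,1100,1600,4.5,5.8,7,8.2,TRUE
chickpea,Pulses,90,130,-2,7,15,25,32,300,450,900,1400,5,6,8,8.6,TRUE
cassava,Roots,180,365,8,15,22,30,38,500,800,2000,3500,4,5,7,8,TRUE
tannia,Roots,240,330,8,15,20,30,36,900,1400,2500,4000,4.5,5.5,6.5,7.5,FALSE
potato,Roots,90,140,-1,7,14,22,28,300,500,1000,1500,4.5,5.5,6.5,7.5,TRUE
cocoyam,Roots,180,300,8,15,21,30,35,800,1300,2500,4000,4.2,5.5,6.5,7.5,TRUE
sweetpotato,Roots,100,160,6,13,20,30,36,400,700,1500,2500,4.5,5.5,6.8,7.8,TRUE
whiteyam,Roots,180,300,8,16,22,31,38,700,1100,2200,3500,4.5,5.5,7,8,TRUE
banana,Banana,300,365,8,16,24,32,38,900,1400,2800,4500,4.5,5.5,7,8,TRUE
enset,Banana,300,365,5,12,17,25,32,900,1300,2400,4000,5,5.8,7,8,FALSE
plantain,Banana,300,365,9,17,24,32,38,1000,1500,2900,4500,4.5,5.5,7,8,TRUE
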