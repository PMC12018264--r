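zone_id,zone_name,belt,tbio_low,tbio_high,frost_free,precip_low,precip_high
1,polar desert,polar,0,1.5,NA,0,Inf
2,subpolar dry tundra,subpolar,1.5,3,NA,0,125
3,subpolar moist tundra,subpolar,1.5,3,NA,125,250
4,subpolar wet tundra,subpolar,1.5,3,NA,250,500
5,subpolar rain tundra,subpolar,1.5,3,NA,500,Inf
6,boreal desert,boreal,3,6,NA,0,125
7,boreal dry scrub,boreal,3,6,NA,125,250
8,boreal moist forest,boreal,3,6,NA,250,500
9,boreal wet forest,boreal,3,6,NA,500,1000
10,boreal rain forest,boreal,3,6,NA,1000,Inf
11,cool temperate desert,cool temperate,6,12,NA,0,125
12,cool temperate desert scrub,cool temperate,6,12,NA,125,250
13,cool temperate steppe,cool temperate,6,12,NA,250,500
14,cool temperate moist forest,cool temperate,6,12,NA,500,1000
15,cool temperate wet forest,cool temperate,6,12,NA,1000,2000
16,cool temperate rain forest,cool temperate,6,12,NA,2000,Inf
17,warm temperate desert,warm temperate,12,24,FALSE,0,125
18,warm temperate desert scrub,warm temperate,12,24,FALSE,125,250
19,warm temperate thorn steppe,warm temperate,12,24,FALSE,250,500
20,warm temperate dry forest,warm temperate,12,24,FALSE,500,1000
21,warm temperate moist forest,warm temperate,12,24,FALSE,1000,2000
22,warm temperate wet forest,warm temperate,12,24,FALSE,2000,4000
23,warm temperate rain forest,warm temperate,12,24,FALSE,4000,Inf
24,subtropical desert,subtropical,12,24,TRUE,0,125
25,subtropical desert scrub,subtropical,12,24,TRUE,125,250
26,subtropical thorn woodland,subtropical,12,24,TRUE,250,500
27,subtropical dry forest,subtropical,12,24,TRUE,500,1000
28,subtropical moist forest,subtropical,12,24,TRUE,1000,2000
29,subtropical wet forest,subtropical,12,24,TRUE,2000,4000
30,subtropical rain forest,subtropical,12,24,TRUE,4000,Inf
31,tropical desert,tropical,24,Inf,NA,0,125
32,tropical desert scrub,tropical,24,Inf,NA,125,250
33,tropical thorn woodland,tropical,24,Inf,NA,250,500
34,tropical very dry forest,tropical,24,Inf,NA,500,1000
35,tropical dry forest,tropical,24,Inf,NA,1000,2000
36,tropical moist forest,tropical,24,Inf,NA,2000,4000
37,tropical wet forest,tropical,24,Inf,NA,4000,8000
38,tropical rain forest,tropical,24,Inf,NA,8000,Inf
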