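area_group,site,n_colonies,density_nests_m2,pairs_mean,pairs_lo,pairs_hi,method
Bellsund,Ingeborgfjellet,15,1.44,35814,24665,47165,density_model
Hornsund,Ariekammen,19,1.99,18064,11669,24704,density_model
Hornsund,Fugleberget,2,1.28,7680,5370,10039,density_model
Hornsund,Hyttevika,9,1.99,370530,239350,506715,density_model
Hornsund,Lechbotnen,7,1.99,30893,19956,42248,density_model
Hornsund,Revdalen,6,1.99,29615,19130,40500,density_model
Hornsund,Rotjesfjellet,16,1.99,68596,44311,93808,density_model
Hornsund,Torbjornsenfjellet,6,1.99,66513,42965,90960,density_model
Isfjorden,Bjorndalen,1,0.58,135,49,227,density_model
Kongsfjorden,Kongsfjorden,1,1.00,3890,3890,3890,fixed_rule
NW Spitsbergen,Amsterdamoya,1,NA,500,500,500,cliff_count
NW Spitsbergen,Fuglesangen,19,1.51,28710,19658,37906,density_model
NW Spitsbergen,Hamburgbukta,11,1.51,36515,25002,48210,density_model
NW Spitsbergen,Magdalenefjorden,18,1.51,18089,12386,23883,density_model
NW Spitsbergen,Nilsenfjellet,7,1.51,8164,5590,10778,density_model
Sjuoyane,Sjuoyane,5,0.20,4821,4821,4821,fixed_rule
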