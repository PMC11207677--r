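parcel,x,y,z
bankssts,60,-45,10
caudalanteriorcingulate,5,20,30
caudalmiddlefrontal,40,10,45
cuneus,8,-80,30
entorhinal,25,-10,-30
fusiform,35,-50,-20
inferiorparietal,45,-65,35
inferiortemporal,50,-40,-25
isthmuscingulate,8,-45,25
lateraloccipital,30,-90,5
lateralorbitofrontal,25,35,-15
lingual,12,-70,-8
medialorbitofrontal,8,40,-15
middletemporal,60,-30,-10
parahippocampal,25,-35,-20
paracentral,8,-25,60
parsopercularis,50,15,15
parsorbitalis,45,35,-8
parstriangularis,48,30,5
pericalcarine,10,-80,10
postcentral,45,-25,50
posteriorcingulate,6,-20,40
precentral,40,-10,50
precuneus,8,-60,45
rostralanteriorcingulate,6,35,10
rostralmiddlefrontal,35,45,25
superiorfrontal,15,25,55
superiorparietal,25,-60,60
superiortemporal,60,-15,0
supramarginal,55,-45,30
frontalpole,12,60,0
temporalpole,35,15,-35
transversetemporal,50,-20,10
insula,38,0,5
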