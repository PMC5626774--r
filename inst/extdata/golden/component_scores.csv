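drug,struct,func,side
thapsigargin,0.25,0.384,0
lycorine,1,0.668,0
carbimazole,0.938,0.554,0
anisomycin,1,0.459,0
perphenazine,1,0.569,0
puromycin,0.75,0.459,0
lasalocid,0.5,0,0
etoposide,0.438,0.518,0.504
irinotecan,0.75,0.572,0
niclosamide,0.938,0.361,0.973
naltrexone,1,0.699,0.829
spiradoline,1,0.769,0
colistin,0,0,0
benzocaine,0.938,0.427,0
rotenone,1,0.263,0
norethisterone,1,0.523,0
alsterpaullone,1,1,0
hesperetin,1,0.411,0
azacitidine,0.75,0.609,0.128
clobetasol,1,0.692,0
acacetin,1,0.312,0
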