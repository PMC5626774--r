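drug,violations
thapsigargin,12
lycorine,0
carbimazole,1
anisomycin,0
perphenazine,0
puromycin,4
lasalocid,8
etoposide,9
irinotecan,4
niclosamide,1
naltrexone,0
spiradoline,0
colistin,16
benzocaine,1
rotenone,0
norethisterone,0
alsterpaullone,0
hesperetin,0
azacitidine,4
clobetasol,0
acacetin,0
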