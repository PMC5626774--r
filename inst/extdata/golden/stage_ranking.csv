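stage,drug,inhib,codres,shift
ipf_vs_normal,lycorine,0.915,0.7,2
ipf_vs_normal,perphenazine,0.949,0.693,0
ipf_vs_normal,carbimazole,0.846,0.637,1
ipf_vs_normal,anisomycin,0.793,0.609,1
ipf_vs_normal,niclosamide,0.331,0.587,6
ipf_vs_normal,puromycin,0.741,0.538,0
ipf_vs_normal,thapsigargin,1,0.527,-6
ipf_vs_normal,alsterpaullone,0.16,0.464,5
ipf_vs_normal,rotenone,0.527,0.463,0
ipf_vs_normal,spiradoline,0.231,0.446,2
ipf_vs_normal,benzocaine,0.394,0.431,-1
ipf_vs_normal,lasalocid,0.706,0.382,-4
ipf_vs_normal,azacitidine,0.108,0.341,1
ipf_vs_normal,etoposide,0.108,0.335,1
ipf_vs_normal,colistin,0.726,0.29,-8
stage1_vs_normal,naltrexone,0.55,0.726,7
stage1_vs_normal,anisomycin,1,0.692,-1
stage1_vs_normal,lycorine,0.656,0.596,3
stage1_vs_normal,carbimazole,0.736,0.593,0
stage1_vs_normal,perphenazine,0.622,0.563,2
stage1_vs_normal,niclosamide,0.266,0.561,7
stage1_vs_normal,benzocaine,0.693,0.55,-2
stage1_vs_normal,spiradoline,0.385,0.508,4
stage1_vs_normal,thapsigargin,0.853,0.468,-6
stage1_vs_normal,puromycin,0.539,0.457,0
stage1_vs_normal,rotenone,0.484,0.446,0
stage1_vs_normal,colistin,0.935,0.374,-10
stage1_vs_normal,azacitidine,0.086,0.332,1
stage1_vs_normal,lasalocid,0.542,0.317,-5
stage1_vs_normal,irinotecan,0.083,0.298,0
stage2_vs_normal,anisomycin,0.92,0.66,2
stage2_vs_normal,niclosamide,0.502,0.655,4
stage2_vs_normal,etoposide,0.7,0.572,2
stage2_vs_normal,alsterpaullone,0.346,0.538,9
stage2_vs_normal,puromycin,0.718,0.529,-1
stage2_vs_normal,thapsigargin,1,0.527,-5
stage2_vs_normal,perphenazine,0.489,0.509,0
stage2_vs_normal,lycorine,0.372,0.482,2
stage2_vs_normal,lasalocid,0.937,0.475,-7
stage2_vs_normal,irinotecan,0.466,0.451,-2
stage2_vs_normal,carbimazole,0.365,0.444,0
stage2_vs_normal,rotenone,0.436,0.427,-3
stage2_vs_normal,spiradoline,0.117,0.401,3
stage2_vs_normal,azacitidine,0.187,0.372,1
stage2_vs_normal,benzocaine,0.198,0.352,-1
stage2_vs_normal,hesperetin,0.115,0.328,1
stage2_vs_normal,colistin,0.356,0.142,-5
stage2_vs_stage1,niclosamide,0.769,0.762,4
stage2_vs_stage1,alsterpaullone,0.809,0.724,2
stage2_vs_stage1,azacitidine,1,0.697,-2
stage2_vs_stage1,irinotecan,0.972,0.653,-2
stage2_vs_stage1,clobetasol,0.743,0.636,2
stage2_vs_stage1,etoposide,0.855,0.634,-3
stage2_vs_stage1,naltrexone,0.281,0.618,7
stage2_vs_stage1,perphenazine,0.73,0.606,0
stage2_vs_stage1,norethisterone,0.744,0.602,-3
stage2_vs_stage1,puromycin,0.689,0.517,-1
stage2_vs_stage1,hesperetin,0.539,0.498,0
stage2_vs_stage1,acacetin,0.567,0.489,-2
stage2_vs_stage1,anisomycin,0.427,0.462,-1
stage2_vs_stage1,spiradoline,0.092,0.391,5
stage2_vs_stage1,carbimazole,0.111,0.343,3
stage2_vs_stage1,rotenone,0.18,0.324,0
stage2_vs_stage1,benzocaine,0.123,0.322,0
stage2_vs_stage1,thapsigargin,0.318,0.254,-5
stage2_vs_stage1,lasalocid,0.215,0.186,-4
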