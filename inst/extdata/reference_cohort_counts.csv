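group,variable,level,count,printed_pct,n_group
included,race,Black,336,5.6,6042
included,race,Other,309,5.1,6042
included,race,White,5072,83.9,6042
included,sex,Female,4379,72.5,6042
included,sex,Male,1579,26.1,6042
included,ethnicity,Hispanic or Latino,376,6.2,6042
included,ethnicity,Not Hispanic or Latino,5590,92.5,6042
included,education,College degree,4317,71.4,6042
included,education,Some college,1346,22.3,6042
included,education,No college,356,5.9,6042
included,cad,Yes,170,2.8,6042
included,cancer,Yes,1429,23.7,6042
included,smoking,>100 cigarettes,1932,32.0,6042
included,alcohol,>=1 drink,5846,96.8,6042
excluded,race,Black,45661,21.9,208164
excluded,race,Other,11112,5.3,208164
excluded,race,White,108141,51.9,208164
excluded,sex,Female,126159,60.6,208164
excluded,sex,Male,77969,37.5,208164
excluded,ethnicity,Hispanic or Latino,41638,20.0,208164
excluded,ethnicity,Not Hispanic or Latino,160368,77.0,208164
excluded,education,College degree,82407,39.6,208164
excluded,education,Some college,53973,25.9,208164
excluded,education,No college,66925,32.2,208164
excluded,cad,Yes,14684,7.1,208164
excluded,cancer,Yes,58050,27.9,208164
excluded,smoking,>100 cigarettes,84466,40.6,208164
excluded,alcohol,>=1 drink,177735,85.4,208164
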