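variable,level,ish_count,ish_pct,death_count,death_pct
total,total,35518,100.0,13416,100.0
sex,female,21092,59.4,4205,31.3
sex,male,14426,40.6,9211,68.7
age,0-34,14241,40.1,2715,20.2
age,35-64,16887,47.5,7340,54.7
age,>=65,4390,12.4,3361,25.1
sex/age,"female, 0-34",9120,25.7,1140,8.5
sex/age,"female, 35-64",9790,27.6,2014,15.0
sex/age,"female, >=65",2182,6.1,1051,7.8
sex/age,"male, 0-34",5121,14.4,1575,11.7
sex/age,"male, 35-64",7097,20.0,5326,39.7
sex/age,"male, >=65",2208,6.2,2310,17.2
mechanism,poisoning,18775,52.9,2577,19.2
mechanism,drowning,690,1.9,876,6.5
mechanism,hanging,1358,3.8,7117,53.0
mechanism,jumping,726,2.0,2483,18.5
mechanism,sharp objects,9791,27.6,151,1.1
mechanism,others,4178,11.8,212,1.6
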