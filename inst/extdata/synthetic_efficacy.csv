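"subgroup","trial","arm","mrs0","mrs1","mrs2","mrs3","mrs4","mrs5","mrs6","n","mean_age"
"synthetic_01","DAWN","MT_SMC",0.0717464417854677,0.130341820202234,0.193382280653516,0.21008436449515,0.202842195800167,0.191602897063464,NA,100,70
"synthetic_01","DAWN","SMC",0.00958403155494595,0.0946050845173492,0.0907981870054416,0.103845833014994,0.216664709697293,0.484502154209977,NA,100,70
"synthetic_02","DEFUSE3","MT_SMC",0.0349134263646344,0.156493173663831,0.107403018343984,0.251082123584238,0.239383708693111,0.098859407216392,0.11186514213381,100,70
"synthetic_02","DEFUSE3","SMC",0.00875587374212878,0.0493844202060729,0.065851840386128,0.144241606668894,0.209733978448171,0.293290877496841,0.228741403051765,100,70
"synthetic_03","DAWN","MT_SMC",0.0532963073858243,0.181633473596585,0.162683679828044,0.237154486759949,0.18561877291586,0.179613279513737,NA,100,70
"synthetic_03","DAWN","SMC",0.018843978078849,0.0523244652760712,0.120078806879583,0.105103915432398,0.294878844439075,0.408769989894023,NA,100,70
"synthetic_04","DEFUSE3","MT_SMC",0.0796052831410865,0.139003352336326,0.158266304507004,0.195936452536998,0.230058604752227,0.108752449798924,0.0883775529274353,100,70
"synthetic_04","DEFUSE3","SMC",0.0408392189756134,0.0857288189819942,0.119668971811778,0.116650449157131,0.167027813414024,0.212812827094477,0.257271900564982,100,70
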