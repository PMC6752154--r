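location,n_provenances,mat_c,mat_sd,mwmt_c,mwmt_sd,mcmt_c,mcmt_sd,td_c,td_sd,map_mm,map_sd,msp_mm,msp_sd,cmd_mm,cmd_sd
Calling Lake (field site),NA,0.6,NA,15.6,NA,-18.0,NA,33.6,NA,491,NA,336,NA,150,NA
Boreal Cordillera,4,-3.3,1.3,13.7,1.2,-22.6,3.3,36.3,4.3,310,46,193,19.6,201,43.5
Boreal Plains,9,-0.6,1.6,17.0,1.4,-21.7,2.5,38.7,2.3,450,66,291,51.3,177,30.4
Boreal Shield,9,0.7,1.0,16.5,0.8,-16.9,2.5,33.5,2.9,922,179,468,66.8,66,52.6
Maritime Mixedwood,3,5.0,0.5,17.4,0.7,-6.2,0.8,23.5,1.3,1246,146,463,31.1,52,16.0
Montane Cordillera,4,1.2,1.6,13.4,0.7,-12.2,3.5,25.6,3.5,702,250,290,77.1,174,66.0
Temperate Mixedwood,4,5.5,0.6,20.1,0.3,-10.9,1.6,31.0,1.6,832,11,384,19.2,192,10.7
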