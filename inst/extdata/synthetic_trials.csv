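participant_id,trial_label,rt_ms,correct,order,timepoint
P00001,04,779.891539846921,TRUE,1,1
P00001,03,776.012000060331,TRUE,2,1
P00001,05,782.048600748302,FALSE,3,1
P00001,06,801.67026716394,TRUE,4,1
P00001,02,753.257072143962,TRUE,5,1
P00001,01,742.039946507986,TRUE,6,1
P00002,06,921.738206496015,FALSE,1,1
P00002,03,787.337198568798,TRUE,2,1
P00002,04,817.258981121826,TRUE,3,1
P00002,02,717.916186619835,FALSE,4,1
P00002,01,681.657325991304,TRUE,5,1
P00002,05,847.050083852985,TRUE,6,1
P00003,01,966.437389317416,TRUE,1,1
P00003,02,1007.98968701341,FALSE,2,1
P00003,06,1207.85488354399,FALSE,3,1
P00003,04,1079.81236738014,FALSE,4,1
P00003,03,1028.83106746526,TRUE,5,1
P00003,05,1126.88121307651,FALSE,6,1
P00004,05,997.38978446464,TRUE,1,1
P00004,06,1055.0876876743,FALSE,2,1
P00004,04,964.772240533156,FALSE,3,1
P00004,01,887.458193659446,TRUE,4,1
P00004,02,910.581861106249,TRUE,5,1
P00004,03,920.771052754667,TRUE,6,1
P00005,03,1151.85850631059,FALSE,1,1
P00005,02,1133.73310722292,FALSE,2,1
P00005,06,1470.46953950054,FALSE,3,1
P00005,05,1356.26522610112,FALSE,4,1
P00005,01,1026.39848533449,TRUE,5,1
P00005,04,1325.49483892731,FALSE,6,1
P00006,02,1180.63983135958,FALSE,1,1
P00006,01,1062.05926693921,TRUE,2,1
P00006,06,1438.60776319909,FALSE,3,1
P00006,04,1220.1790867136,FALSE,4,1
P00006,05,1315.06104466584,FALSE,5,1
P00006,03,1266.38282950365,TRUE,6,1
P00007,04,1082.77386437959,FALSE,1,1
P00007,05,1080.49211005703,TRUE,2,1
P00007,03,1060.94969010006,TRUE,3,1
P00007,01,1042.63717037866,TRUE,4,1
P00007,02,1047.25799585217,TRUE,5,1
P00007,06,1103.25045978641,FALSE,6,1
P00008,03,943.335736425625,TRUE,1,1
P00008,01,903.018866232319,TRUE,2,1
P00008,05,982.71531868073,TRUE,3,1
P00008,06,1005.7400088792,FALSE,4,1
P00008,02,923.484881141781,TRUE,5,1
P00008,04,954.267323274585,TRUE,6,1
P00009,04,1810.2376875532,FALSE,1,1
P00009,05,1845.6842332907,TRUE,2,1
P00009,06,1978.59097561711,FALSE,3,1
P00009,02,1645.06212493576,FALSE,4,1
P00009,01,1588.32225668577,TRUE,5,1
P00009,03,1781.15273036176,FALSE,6,1
P00010,02,1010.72622623942,TRUE,1,1
P00010,05,1076.60123179314,FALSE,2,1
P00010,04,1071.22614258438,TRUE,3,1
P00010,01,1013.76085231496,TRUE,4,1
P00010,03,1051.9880049875,TRUE,5,1
P00010,06,1150.75748579619,TRUE,6,1
P00011,06,1068.81998759784,FALSE,1,1
P00011,02,1000.2351794209,TRUE,2,1
P00011,04,1024.79972399824,TRUE,3,1
P00011,03,1023.69235894269,TRUE,4,1
P00011,05,1051.02763462446,TRUE,5,1
P00011,01,982.139270000614,TRUE,6,1
P00012,02,1021.05067343956,TRUE,1,1
P00012,03,1100.24597708204,TRUE,2,1
P00012,05,1202.21134615774,FALSE,3,1
P00012,06,1421.91035712264,FALSE,4,1
P00012,04,1131.22552297978,TRUE,5,1
P00012,01,955.764008324412,TRUE,6,1
P00013,05,835.311477418755,FALSE,1,1
P00013,01,666.734813180111,TRUE,2,1
P00013,04,827.831958807037,FALSE,3,1
P00013,06,945.232317821135,TRUE,4,1
P00013,02,685.961848756116,FALSE,5,1
P00013,03,744.732426849237,TRUE,6,1
P00014,06,871.356622641517,FALSE,1,1
P00014,03,760.292868832842,TRUE,2,1
P00014,02,799.698665899271,TRUE,3,1
P00014,01,685.267573150607,TRUE,4,1
P00014,05,829.851832279205,FALSE,5,1
P00014,04,835.029981934966,TRUE,6,1
P00015,04,1135.51222230001,TRUE,1,1
P00015,01,1080.32369646858,TRUE,2,1
P00015,03,1109.2531918888,FALSE,3,1
P00015,02,1101.17695279295,TRUE,4,1
P00015,06,1168.6554542497,FALSE,5,1
P00015,05,1142.61185847015,TRUE,6,1
P00016,01,963.795898483831,TRUE,1,1
P00016,06,1220.29021665885,FALSE,2,1
P00016,04,1223.93079117746,FALSE,3,1
P00016,05,1070.42457921754,FALSE,4,1
P00016,02,1023.96802341077,TRUE,5,1
P00016,03,1073.97288095084,TRUE,6,1
P00017,05,778.569116271388,FALSE,1,1
P00017,04,796.645180757812,TRUE,2,1
P00017,01,740.624975735435,TRUE,3,1
P00017,03,758.938262704732,TRUE,4,1
P00017,02,747.885654838755,TRUE,5,1
P00017,06,802.382838969456,FALSE,6,1
P00018,03,686.755062782374,TRUE,1,1
P00018,04,770.821949116555,TRUE,2,1
P00018,02,694.40695377429,TRUE,3,1
P00018,05,727.735921751426,TRUE,4,1
P00018,01,639.494029614042,TRUE,5,1
P00018,06,867.527775608987,FALSE,6,1
P00019,02,724.038888756673,TRUE,1,1
P00019,05,794.884817119662,FALSE,2,1
P00019,01,694.483803573528,TRUE,3,1
P00019,04,807.176729719696,TRUE,4,1
P00019,03,717.059203211107,TRUE,5,1
P00019,06,797.660830384498,FALSE,6,1
P00020,02,942.915534402421,TRUE,1,1
P00020,01,897.298940547044,TRUE,2,1
P00020,06,1131.38645560314,FALSE,3,1
P00020,05,1117.20049823377,FALSE,4,1
P00020,04,1058.96381391561,FALSE,5,1
P00020,03,999.636603194761,TRUE,6,1
P00021,05,1050.82626557663,FALSE,1,1
P00021,03,925.953837319369,FALSE,2,1
P00021,04,893.83578778272,FALSE,3,1
P00021,06,1107.64933165049,FALSE,4,1
P00021,02,826.779000364195,TRUE,5,1
P00021,01,773.487890761541,TRUE,6,1
P00022,05,1184.59886028707,FALSE,1,1
P00022,03,1022.28759923578,FALSE,2,1
P00022,06,1242.09642253375,FALSE,3,1
P00022,04,1092.92500494171,FALSE,4,1
P00022,02,1038.66996384735,TRUE,5,1
P00022,01,964.577757478189,FALSE,6,1
P00023,05,1122.80457477993,TRUE,1,1
P00023,04,1015.67301713098,FALSE,2,1
P00023,06,1164.5304333654,FALSE,3,1
P00023,01,830.944605888439,TRUE,4,1
P00023,02,942.236814993122,TRUE,5,1
P00023,03,996.536906622124,TRUE,6,1
P00024,03,886.919110761857,FALSE,1,1
P00024,04,928.252814096872,TRUE,2,1
P00024,05,966.942633418639,FALSE,3,1
P00024,01,822.748254801895,TRUE,4,1
P00024,06,986.167235611321,FALSE,5,1
P00024,02,839.958598521069,TRUE,6,1
P00025,01,812.025136525627,TRUE,1,1
P00025,03,859.418484906893,TRUE,2,1
P00025,05,917.465751367694,FALSE,3,1
P00025,02,839.824314526115,TRUE,4,1
P00025,04,882.355134888178,TRUE,5,1
P00025,06,948.219777581761,FALSE,6,1
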