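id,group,sex,age_y,body_weight_kg,bmi_kg_m2,serum_retinol_umol_l,liver_weight_g
US1,US,M,47,72.6,29.3,2.34,1375
US2,US,F,55,57.7,25.7,1.64,1196
US3,US,F,44,82.3,30.7,1.44,1494
US4,US,F,70,54.5,22.0,1.41,1192
US5,US,F,57,60.4,27.9,2.06,1213
US6,US,M,68,79.5,25.9,1.41,1519
US7,US,F,67,65.8,26.6,1.85,1309
CH1,CH,M,50,59.8,23.9,1.40,1251
CH2,CH,M,60,63.8,21.6,1.35,1347
CH3,CH,F,57,77.0,28.6,1.10,1446
CH4,CH,F,51,56.9,23.7,0.932,1208
CH5,CH,F,55,77.4,29.9,0.850,1436
CH6,CH,M,53,72.0,30.0,1.58,1359
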