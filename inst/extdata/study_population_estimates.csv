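group,treatment,U1_umol_d,M5_umol,M6_umol,M7_umol,TBS_umol,DR_umol_d,days_of_stores_d,liver_va_umol_g
US,1EV,16.2,5,783,NA,783,12.2,64.4,0.533
US,2EV,14.4,5,926,29.7,956,10.8,88.5,0.65
US,2EV_DI,2.79,5,1926,130,2056,2.1,981,1.4
CH,1EV,6.84,3.43,219,NA,219,5.13,42.8,0.148
CH,2EV,5.86,3.43,297,19.6,317,4.39,72.1,0.213
CH,2EV_DI,2.94,3.43,564,30.1,594,2.21,269,0.4
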