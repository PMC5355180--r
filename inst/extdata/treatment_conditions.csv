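site,treatment,temp_c,ph_t,pco2_uatm,omega_a,alk_umol_kg,salinity
FC,8.03,14.8,8.02,428,2.16,2246,33.0
FC,7.76,14.7,7.76,828,1.28,2246,33.0
FC,7.61,14.8,7.61,1213,0.93,2245,33.0
BMR,8.03,14.3,8.06,378,2.33,2239,33.1
BMR,7.76,14.4,7.75,857,1.22,2240,33.0
BMR,7.61,14.4,7.60,1233,0.90,2244,33.0
SB,8.03,15.0,8.01,435,2.11,2227,33.0
SB,7.87,15.0,7.87,623,1.61,2230,33.0
SB,7.76,15.0,7.76,832,1.27,2226,33.0
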