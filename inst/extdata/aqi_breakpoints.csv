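pollutant,units,bp_lo,bp_hi,i_lo,i_hi,truncation_decimals
O3,ppm_8hr,0.000,0.054,0,50,3
O3,ppm_8hr,0.055,0.070,51,100,3
O3,ppm_8hr,0.071,0.085,101,150,3
O3,ppm_8hr,0.086,0.105,151,200,3
O3,ppm_8hr,0.106,0.200,201,300,3
NO2,ppb_1hr,0,53,0,50,0
NO2,ppb_1hr,54,100,51,100,0
NO2,ppb_1hr,101,360,101,150,0
NO2,ppb_1hr,361,649,151,200,0
NO2,ppb_1hr,650,1249,201,300,0
NO2,ppb_1hr,1250,1649,301,400,0
NO2,ppb_1hr,1650,2049,401,500,0
SO2,ppb_1hr,0,35,0,50,0
SO2,ppb_1hr,36,75,51,100,0
SO2,ppb_1hr,76,185,101,150,0
SO2,ppb_1hr,186,304,151,200,0
SO2,ppb_1hr,305,604,201,300,0
SO2,ppb_1hr,605,804,301,400,0
SO2,ppb_1hr,805,1004,401,500,0
CO,ppm_8hr,0.0,4.4,0,50,1
CO,ppm_8hr,4.5,9.4,51,100,1
CO,ppm_8hr,9.5,12.4,101,150,1
CO,ppm_8hr,12.5,15.4,151,200,1
CO,ppm_8hr,15.5,30.4,201,300,1
CO,ppm_8hr,30.5,40.4,301,400,1
CO,ppm_8hr,40.5,50.4,401,500,1
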