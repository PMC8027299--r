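location,metric,year_start,value_start,year_end,value_end,published_apc
National,asir,1990,13,2016,44,4.8
National,asdr,1990,5.7,2015,5.1,-0.5
National,asyr,1990,85.1,2015,151.1,2.3
National,new_cases,1990,1452,2016,14217,NA
National,age_specific_rate_85plus,2016,362.6,2016,362.6,NA
National,age_specific_rate_15_19,2016,3.6,2016,3.6,NA
Alborz,asir,1990,11.1,2016,38.7,4.9
Alborz,asdr,1990,4.3,2015,10,3.4
Zanjan,asir,1990,12,2016,14.6,0.8
Semnan,asir,1990,9.1,2016,45,6.3
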