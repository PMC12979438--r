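group,context,lambda,k,c,l50_printed
GY,population,139.35,329.10,-137.65,1.54
HT,population,1.97,6.11,-0.26,1.59
CJ,population,49.17,130.19,-47.33,1.69
TZ,population,62.61,163.43,-61.00,1.47
TY,population,216.71,551.84,-215.10,1.46
BY,population,1.96,5.54,-0.22,1.61
2008,collection_year,1.03,3.56,-0.94,0
2015,collection_year,0.97,3.93,-0.75,0.10
2019,collection_year,64.12,180.11,-62.66,1.20
2020,collection_year,24.23,89.61,-22.59,1.46
2021,collection_year,68.35,202.70,-66.69,1.45
2022,collection_year,119.10,225.66,-116.82,2.06
2023,collection_year,1.03,3.56,-0.94,2.39
Abandoned farmland,habitat,22.46,63.61,-20.74,1.59
Grassland,habitat,275.88,469.10,-274.49,1.36
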