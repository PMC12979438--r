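age_years,l50_days
0,2.39
1,2.06
2,1.45
3,1.46
4,1.20
8,0.10
15,0
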