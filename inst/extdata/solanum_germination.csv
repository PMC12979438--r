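cohort,replicate,percent_germinated
2008,1,0.00
2008,2,0.00
2008,3,0.00
2008,4,0.00
2008,5,0.00
2008,6,0.00
2015,1,10.00
2015,2,6.67
2015,3,13.33
2015,4,6.67
2015,5,16.67
2015,6,10.00
2023,1,83.33
2023,2,93.33
2023,3,86.67
2023,4,80.00
2023,5,83.33
2023,6,93.33
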