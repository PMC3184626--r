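sex,age_band,n_patients,pct_discontinued,median_illness_months
male,18-21,26,40,21
male,22-29,72,48,30
male,30-39,128,53,72
male,40-49,127,56,60
male,50-59,116,65,48
male,60-64,32,59,31
female,18-21,150,25,36
female,22-29,294,43,26
female,30-39,461,43,36
female,40-49,411,53,48
female,50-59,281,61,55
female,60-64,72,60,87
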