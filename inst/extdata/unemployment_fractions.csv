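sex,n,mean_fraction,ci_low,ci_high
male,22,0.52,0.38,0.66
female,38,0.47,0.35,0.59
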