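sex,age_band,count
men,65-69,3900000
men,70-74,4200000
men,75-79,3200000
men,80-84,2400000
women,65-69,4100000
women,70-74,4600000
women,75-79,3800000
women,80-84,3200000
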