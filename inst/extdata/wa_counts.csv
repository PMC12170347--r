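source,age_group,count
census,age0_9,302
census,age10_14,498
census,age15_19,712
wacdd,age0_9,285
wacdd,age10_14,384
ndss,age0_9,310
ndss,age10_19,1410
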