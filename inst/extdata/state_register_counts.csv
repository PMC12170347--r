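state,age_group,census,ndss
NSW,age0_9,766,830
VIC,age0_9,689,750
QLD,age0_9,560,570
WA,age0_9,302,310
SA,age0_9,193,190
TAS,age0_9,71,80
NT,age0_9,20,NA
ACT,age0_9,44,50
NSW,age10_19,3494,3770
VIC,age10_19,2746,3080
QLD,age10_19,2505,2970
WA,age10_19,1210,1410
SA,age10_19,887,980
TAS,age10_19,272,310
NT,age10_19,144,160
ACT,age10_19,211,220
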