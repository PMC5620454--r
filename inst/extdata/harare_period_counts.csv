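label,months,count
1 month,1,85
3 months,3,560
6 months,6,952
12 months,12,1542
24 months,24,2227
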