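scale,pre_median,post_median
HAMA,7.50,5.50
HAMD,10.00,6.00
LEDD,725.85,225.00
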