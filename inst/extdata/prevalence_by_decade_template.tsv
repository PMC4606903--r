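age_lo	age_hi	prevalence
50	59	0.004
60	69	0.010
70	79	0.050
80	89	0.120
90	109	0.200
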