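horizon_months,mean_diff,se_diff
3,0.008,0.009
6,0.023,0.027
9,0.039,0.046
12,0.054,0.064
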