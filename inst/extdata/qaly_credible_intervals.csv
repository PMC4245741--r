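method,horizon_months,arm,mean,ci_low,ci_high
endpoint,3,control,0.112,0.102,0.123
endpoint,3,intervention,0.164,0.159,0.168
auc,3,control,0.120,0.077,0.160
auc,3,intervention,0.156,0.136,0.176
auc,6,control,0.231,0.138,0.318
auc,6,intervention,0.312,0.267,0.355
auc,9,control,0.344,0.199,0.475
auc,9,intervention,0.470,0.398,0.537
auc,12,control,0.454,0.247,0.623
auc,12,intervention,0.629,0.526,0.718
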