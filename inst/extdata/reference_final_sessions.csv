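cage,n_trials,hit_pct,fa_pct,early_pct,dprime,median_latency_s
1,9476,4.1,0.5,1.8,1.1,1.70
2,8537,6.4,0.7,3.0,0.87,1.60
3,9623,5.0,0.2,1.1,0.9,1.67
4,9719,5.2,0.3,0.9,1.3,1.73
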