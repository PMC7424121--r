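condition,morph_pct,mean_rt_s,ci_low,ci_high
unfamiliar_familiar,10,0.76,0.70,0.83
unfamiliar_familiar,20,0.80,0.74,0.88
unfamiliar_familiar,30,0.83,0.77,0.89
unfamiliar_familiar,40,0.88,0.82,0.94
unfamiliar_familiar,60,0.85,0.79,0.90
unfamiliar_familiar,70,0.78,0.73,0.84
unfamiliar_familiar,80,0.75,0.69,0.82
unfamiliar_familiar,90,0.74,0.68,0.81
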