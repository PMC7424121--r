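condition,morph_pct,mean_rt_s,ci_low,ci_high
unfamiliar_unfamiliar,10,0.67,0.63,0.72
unfamiliar_unfamiliar,20,0.71,0.66,0.77
unfamiliar_unfamiliar,30,0.75,0.69,0.81
unfamiliar_unfamiliar,40,0.83,0.76,0.91
unfamiliar_unfamiliar,60,0.83,0.76,0.91
unfamiliar_unfamiliar,70,0.75,0.69,0.82
unfamiliar_unfamiliar,80,0.71,0.66,0.77
unfamiliar_unfamiliar,90,0.67,0.63,0.72
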