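condition,morph_pct,mean_pct,ci_low,ci_high,n
unfamiliar_unfamiliar,10,4.8,1.7,9.4,540
unfamiliar_unfamiliar,20,5.9,2.4,10.2,540
unfamiliar_unfamiliar,30,9.2,5.2,13.9,540
unfamiliar_unfamiliar,40,20.2,15.6,25.1,540
unfamiliar_unfamiliar,50,50.0,44.6,55.2,540
unfamiliar_unfamiliar,60,79.8,74.9,84.4,540
unfamiliar_unfamiliar,70,90.8,86.1,94.8,540
unfamiliar_unfamiliar,80,94.1,89.8,97.6,540
unfamiliar_unfamiliar,90,95.2,90.6,98.3,540
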