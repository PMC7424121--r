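condition,morph_pct,mean_pct,ci_low,ci_high,n
unfamiliar_familiar,10,5.4,2.8,8.1,540
unfamiliar_familiar,20,6.3,3.1,10.0,540
unfamiliar_familiar,30,7.5,4.8,10.3,540
unfamiliar_familiar,40,16.3,11.7,21.5,540
unfamiliar_familiar,50,41.3,34.6,47.4,540
unfamiliar_familiar,60,79.1,73.1,83.7,540
unfamiliar_familiar,70,91.4,87.6,94.6,540
unfamiliar_familiar,80,95.4,92.4,98.0,540
unfamiliar_familiar,90,97.0,94.1,98.9,540
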