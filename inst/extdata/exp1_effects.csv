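condition,reference,morph_pct,effect,ci_low,ci_high
unfamiliar_familiar,unfamiliar_unfamiliar,10,-0.6,-3.5,2.8
unfamiliar_familiar,unfamiliar_unfamiliar,20,-0.4,-3.2,2.1
unfamiliar_familiar,unfamiliar_unfamiliar,30,1.7,-1.4,5.0
unfamiliar_familiar,unfamiliar_unfamiliar,40,3.9,2.5,10.0
unfamiliar_familiar,unfamiliar_unfamiliar,50,8.7,1.1,17.6
unfamiliar_familiar,unfamiliar_unfamiliar,60,0.7,-5.5,7.3
unfamiliar_familiar,unfamiliar_unfamiliar,70,-0.6,-4.4,2.7
unfamiliar_familiar,unfamiliar_unfamiliar,80,-1.2,-4.5,1.9
unfamiliar_familiar,unfamiliar_unfamiliar,90,-1.8,-4.3,0.4
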