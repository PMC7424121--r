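condition,morph_pct,mean_pct,ci_low,ci_high,n
stranger_friend,10,3.2,1.8,4.5,600
stranger_friend,20,4.5,3.0,6.2,600
stranger_friend,30,4.7,3.2,6.4,600
stranger_friend,40,12.8,10.3,15.3,600
stranger_friend,50,36.4,32.7,39.3,600
stranger_friend,60,77.9,74.8,81.0,600
stranger_friend,70,94.3,92.5,96.2,600
stranger_friend,80,97.5,96.2,98.7,600
stranger_friend,90,98.0,96.8,99.0,600
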