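condition,morph_pct,mean_pct,ci_low,ci_high,n
stranger_stranger,10,11.1,8.1,14.1,150
stranger_stranger,20,14.7,11.0,18.3,150
stranger_stranger,30,14.0,10.7,17.7,150
stranger_stranger,40,27.4,22.7,32.1,150
stranger_stranger,50,50.0,50,50,150
stranger_stranger,60,72.6,67.9,77.3,150
stranger_stranger,70,86.0,82.3,89.3,150
stranger_stranger,80,85.3,81.7,89.0,150
stranger_stranger,90,88.9,85.9,91.9,150
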