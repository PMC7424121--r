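condition,morph_pct,mean_pct,ci_low,ci_high,n
stranger_self,10,2.4,0.7,4.4,300
stranger_self,20,2.7,1.0,4.8,300
stranger_self,30,4.7,2.7,7.1,300
stranger_self,40,11.4,8.4,14.4,300
stranger_self,50,30.2,26.2,34.6,300
stranger_self,60,59.3,54.6,64.0,300
stranger_self,70,86.0,82.3,89.3,300
stranger_self,80,85.3,81.7,89.0,300
stranger_self,90,88.9,85.9,91.9,300
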