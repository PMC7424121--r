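condition,morph_pct,mean_pct,ci_low,ci_high,n
friend_self,10,2.7,1.0,4.3,300
friend_self,20,2.0,0.7,3.7,300
friend_self,30,5.4,3.0,8.0,300
friend_self,40,17.4,13.7,21.4,300
friend_self,50,37.4,32.6,42.4,300
friend_self,60,68.1,63.1,72.8,300
friend_self,70,91.9,88.9,94.9,300
friend_self,80,97.3,95.3,98.9,300
friend_self,90,98.3,96.9,99.7,300
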