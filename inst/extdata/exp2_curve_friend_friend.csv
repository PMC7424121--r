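condition,morph_pct,mean_pct,ci_low,ci_high,n
friend_friend,10,3.0,1.3,5.0,150
friend_friend,20,2.4,1.0,4.1,150
friend_friend,30,5.0,2.7,7.4,150
friend_friend,40,17.9,13.8,22.0,150
friend_friend,50,50.0,50,50,150
friend_friend,60,82.2,78.1,86.2,150
friend_friend,70,95.0,92.6,97.3,150
friend_friend,80,97.6,95.9,99.0,150
friend_friend,90,97.0,95.0,98.6,150
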