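condition,morph_pct,mean_rt_s,ci_low,ci_high
stranger_friend,10,0.70,0.67,0.74
stranger_friend,20,0.72,0.69,0.74
stranger_friend,30,0.74,0.71,0.76
stranger_friend,40,0.80,0.77,0.84
stranger_friend,60,0.75,0.73,0.78
stranger_friend,70,0.71,0.68,0.74
stranger_friend,80,0.71,0.68,0.74
stranger_friend,90,0.66,0.65,0.68
stranger_self,10,0.69,0.66,0.73
stranger_self,20,0.73,0.68,0.78
stranger_self,30,0.75,0.71,0.80
stranger_self,40,0.75,0.71,0.79
stranger_self,60,0.79,0.72,0.87
stranger_self,70,0.74,0.70,0.79
stranger_self,80,0.64,0.62,0.67
stranger_self,90,0.67,0.63,0.72
friend_self,10,0.74,0.69,0.79
friend_self,20,0.71,0.67,0.75
friend_self,30,0.70,0.67,0.73
friend_self,40,0.83,0.77,0.90
friend_self,60,0.78,0.73,0.84
friend_self,70,0.71,0.67,0.74
friend_self,80,0.70,0.66,0.74
friend_self,90,0.68,0.64,0.73
stranger_stranger,10,0.78,0.75,0.82
stranger_stranger,20,0.77,0.74,0.80
stranger_stranger,30,0.88,0.82,0.95
stranger_stranger,40,0.96,0.88,1.05
stranger_stranger,60,0.91,0.83,0.99
stranger_stranger,70,0.83,0.77,0.90
stranger_stranger,80,0.80,0.75,0.85
stranger_stranger,90,0.76,0.71,0.83
friend_friend,10,0.67,0.63,0.73
friend_friend,20,0.69,0.64,0.75
friend_friend,30,0.72,0.68,0.76
friend_friend,40,0.80,0.75,0.85
friend_friend,60,0.79,0.73,0.85
friend_friend,70,0.71,0.67,0.76
friend_friend,80,0.67,0.64,0.70
friend_friend,90,0.70,0.67,0.75
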