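condition,reference,morph_pct,effect,ci_low,ci_high
stranger_friend,stranger_stranger,10,-7.9,-11.3,-4.6
stranger_friend,stranger_stranger,20,-10.1,-14.3,-6.1
stranger_friend,stranger_stranger,30,-9.3,-13.2,-5.5
stranger_friend,stranger_stranger,40,-14.6,-19.8,-9.3
stranger_friend,stranger_stranger,50,-13.6,-17.1,-9.9
stranger_friend,stranger_stranger,60,5.3,-0.3,10.8
stranger_friend,stranger_stranger,70,8.3,4.5,12.3
stranger_friend,stranger_stranger,80,12.6,8.3,16.2
stranger_friend,stranger_stranger,90,9.1,5.9,12.3
stranger_self,stranger_stranger,10,-8.7,-12.12,-5.4
stranger_self,stranger_stranger,20,-12.0,-16.0,-7.9
stranger_self,stranger_stranger,30,-9.3,-13.3,-5.0
stranger_self,stranger_stranger,40,-16.1,-21.7,-10.7
stranger_self,stranger_stranger,50,-19.8,-23.8,-15.4
stranger_self,stranger_stranger,60,-13.3,-20.0,-6.6
stranger_self,stranger_stranger,70,2.6,-2.1,7.3
stranger_self,stranger_stranger,80,12.0,8.0,16.0
stranger_self,stranger_stranger,90,8.7,5.4,12.1
friend_self,friend_friend,10,-0.3,-3.0,2.0
friend_self,friend_friend,20,-0.4,-2.7,2.0
friend_self,friend_friend,30,0.3,-3.0,3.7
friend_self,friend_friend,40,-0.5,-6.2,5.3
friend_self,friend_friend,50,-12.6,-17.3,-7.6
friend_self,friend_friend,60,-14.0,-20.4,-8.0
friend_self,friend_friend,70,-3.1,-7.1,0.6
friend_self,friend_friend,80,-0.3,-2.7,2.0
friend_self,friend_friend,90,1.3,-1.0,3.8
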