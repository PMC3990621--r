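id,label,phase
1,shoulders parallel to target line,preparation
2,align club face square to target line,preparation
3,grip check,preparation
4,look to the hole,preparation
5,rotate shoulders away from the ball,backswing
6,keep arms-shoulder triangle,backswing
7,smooth transition,backswing
8,rotate shoulders towards the ball,forward_swing
9,accelerate club,forward_swing
10,impact with the ball,impact
11,club face square to target line at impact,impact
12,follow-through,impact
13,rotate shoulders through the ball,impact
14,decelerate club,attenuation
15,direct clubhead to planned position,attenuation
16,look to the outcome,attenuation
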