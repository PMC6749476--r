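boundary,side,vertex,reference_mgdl,measured_mgdl
AB,upper,1,0,50
AB,upper,2,30,50
AB,upper,3,140,170
AB,upper,4,280,380
AB,upper,5,430,550
AB,lower,1,50,0
AB,lower,2,50,30
AB,lower,3,170,145
AB,lower,4,385,300
AB,lower,5,550,450
BC,upper,1,0,60
BC,upper,2,30,60
BC,upper,3,50,80
BC,upper,4,70,110
BC,upper,5,260,550
BC,lower,1,120,0
BC,lower,2,120,30
BC,lower,3,260,130
BC,lower,4,550,250
CD,upper,1,0,100
CD,upper,2,25,100
CD,upper,3,50,125
CD,upper,4,80,215
CD,upper,5,125,550
CD,lower,1,250,0
CD,lower,2,250,40
CD,lower,3,550,150
DE,upper,1,0,150
DE,upper,2,35,155
DE,upper,3,50,550
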