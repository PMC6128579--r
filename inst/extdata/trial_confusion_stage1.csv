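predicted,feeding,lying,standing,lying_down,standing_up,normal_walking,active_walking
feeding,809,157,517,2,0,76,0
lying,60,2098,38,1,1,15,2
standing,559,295,785,0,1,44,1
lying_down,4,5,0,155,9,6,8
standing_up,1,3,1,13,128,17,11
normal_walking,38,1,13,7,2,987,16
active_walking,0,0,0,2,10,3,311
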