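behavior,original,kept,lt4s,s4,s5,s6,s7,s8,gt8
feeding,5239,3676,401,535,627,614,524,607,1931
lying,7857,6398,353,417,689,732,748,636,4282
standing,4355,3386,37,369,563,452,513,528,1893
lying_down,1172,449,2,207,514,327,103,15,4
standing_up,1322,378,8,173,763,304,58,14,2
normal_walking,4075,2870,267,476,462,739,642,628,861
active_walking,1901,873,167,372,489,517,321,26,9
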