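genotype,environment,pot,seeds_planted,seedlings_retained,adults,seeds_produced
a,toy_lowdens,1,10,1,1,100
a,toy_lowdens,2,10,1,1,100
a,toy_lowdens,3,10,1,1,100
a,toy_lowdens,4,10,1,1,100
a,toy_lowdens,5,10,1,1,100
a,toy_lowdens,6,10,1,1,100
a,toy_lowdens,7,10,1,1,100
a,toy_lowdens,8,10,1,1,100
a,toy_lowdens,9,10,1,1,100
a,toy_lowdens,10,10,1,1,100
a,toy_lowdens,11,10,1,1,100
a,toy_lowdens,12,10,1,1,100
a,toy_lowdens,13,10,1,1,100
a,toy_lowdens,14,10,1,1,100
a,toy_lowdens,15,10,1,1,100
a,toy_lowdens,16,10,1,1,100
a,toy_lowdens,17,10,1,1,100
a,toy_lowdens,18,10,1,1,100
a,toy_lowdens,19,10,1,1,100
a,toy_lowdens,20,10,1,1,100
a,toy_lowdens,21,10,1,1,100
a,toy_lowdens,22,10,1,1,100
a,toy_lowdens,23,10,1,1,100
a,toy_lowdens,24,10,1,1,100
a,toy_lowdens,25,10,1,1,100
a,toy_lowdens,26,10,1,1,100
a,toy_lowdens,27,10,1,1,100
a,toy_lowdens,28,10,1,1,100
a,toy_lowdens,29,10,1,1,100
a,toy_lowdens,30,10,1,1,100
a,toy_lowdens,31,10,1,1,100
a,toy_lowdens,32,10,1,1,100
a,toy_lowdens,33,10,1,1,100
a,toy_lowdens,34,10,1,1,100
a,toy_lowdens,35,10,1,1,100
a,toy_lowdens,36,10,1,1,100
a,toy_lowdens,37,10,1,1,100
a,toy_lowdens,38,10,1,1,100
a,toy_lowdens,39,10,1,1,100
a,toy_lowdens,40,10,1,1,100
a,toy_lowdens,41,10,1,1,100
a,toy_lowdens,42,10,1,1,100
a,toy_lowdens,43,10,1,1,100
a,toy_lowdens,44,10,1,1,100
a,toy_lowdens,45,10,1,1,100
a,toy_lowdens,46,10,1,1,100
a,toy_lowdens,47,10,1,1,100
a,toy_lowdens,48,10,1,1,100
a,toy_lowdens,49,10,1,1,100
a,toy_lowdens,50,10,1,1,100
a,toy_lowdens,51,10,1,1,100
a,toy_lowdens,52,10,1,1,100
a,toy_lowdens,53,10,1,1,100
a,toy_lowdens,54,10,1,1,100
a,toy_lowdens,55,10,1,1,100
a,toy_lowdens,56,10,1,1,100
a,toy_lowdens,57,10,1,1,100
a,toy_lowdens,58,10,1,1,100
a,toy_lowdens,59,10,1,1,100
a,toy_lowdens,60,10,1,1,100
a,toy_lowdens,61,10,1,1,100
a,toy_lowdens,62,10,1,1,100
a,toy_lowdens,63,10,1,1,100
a,toy_lowdens,64,10,1,1,100
a,toy_lowdens,65,10,1,1,100
a,toy_lowdens,66,10,1,1,100
a,toy_lowdens,67,10,1,1,100
a,toy_lowdens,68,10,1,1,100
a,toy_lowdens,69,10,1,1,100
a,toy_lowdens,70,10,1,1,100
a,toy_lowdens,71,10,1,1,100
a,toy_lowdens,72,10,1,1,100
a,toy_lowdens,73,10,1,1,100
a,toy_lowdens,74,10,1,1,100
a,toy_lowdens,75,10,1,1,100
a,toy_lowdens,76,10,1,1,100
a,toy_lowdens,77,10,1,1,100
a,toy_lowdens,78,10,1,1,100
a,toy_lowdens,79,10,1,1,100
a,toy_lowdens,80,10,1,1,100
a,toy_lowdens,81,10,1,1,100
a,toy_lowdens,82,10,1,1,100
a,toy_lowdens,83,10,1,1,100
a,toy_lowdens,84,10,1,1,100
a,toy_lowdens,85,10,1,1,100
a,toy_lowdens,86,10,1,1,100
a,toy_lowdens,87,10,1,1,100
a,toy_lowdens,88,10,1,1,100
a,toy_lowdens,89,10,1,1,100
a,toy_lowdens,90,10,1,1,100
a,toy_lowdens,91,10,1,0,0
a,toy_lowdens,92,10,1,0,0
a,toy_lowdens,93,10,1,0,0
a,toy_lowdens,94,10,1,0,0
a,toy_lowdens,95,10,1,0,0
a,toy_lowdens,96,10,1,0,0
a,toy_lowdens,97,10,1,0,0
a,toy_lowdens,98,10,1,0,0
a,toy_lowdens,99,10,1,0,0
a,toy_lowdens,100,10,1,0,0
b,toy_lowdens,1,10,1,1,100
b,toy_lowdens,2,10,1,1,100
b,toy_lowdens,3,10,1,1,100
b,toy_lowdens,4,10,1,1,100
b,toy_lowdens,5,10,1,1,100
b,toy_lowdens,6,10,1,1,100
b,toy_lowdens,7,10,1,1,100
b,toy_lowdens,8,10,1,1,100
b,toy_lowdens,9,10,1,1,100
b,toy_lowdens,10,10,1,1,100
b,toy_lowdens,11,10,1,1,100
b,toy_lowdens,12,10,1,1,100
b,toy_lowdens,13,10,1,1,100
b,toy_lowdens,14,10,1,1,100
b,toy_lowdens,15,10,1,1,100
b,toy_lowdens,16,10,1,1,100
b,toy_lowdens,17,10,1,1,100
b,toy_lowdens,18,10,1,1,100
b,toy_lowdens,19,10,1,1,100
b,toy_lowdens,20,10,1,1,100
b,toy_lowdens,21,10,1,1,100
b,toy_lowdens,22,10,1,1,100
b,toy_lowdens,23,10,1,1,100
b,toy_lowdens,24,10,1,1,100
b,toy_lowdens,25,10,1,1,100
b,toy_lowdens,26,10,1,1,100
b,toy_lowdens,27,10,1,1,100
b,toy_lowdens,28,10,1,1,100
b,toy_lowdens,29,10,1,1,100
b,toy_lowdens,30,10,1,1,100
b,toy_lowdens,31,10,1,1,100
b,toy_lowdens,32,10,1,1,100
b,toy_lowdens,33,10,1,1,100
b,toy_lowdens,34,10,1,1,100
b,toy_lowdens,35,10,1,1,100
b,toy_lowdens,36,10,1,1,100
b,toy_lowdens,37,10,1,1,100
b,toy_lowdens,38,10,1,1,100
b,toy_lowdens,39,10,1,1,100
b,toy_lowdens,40,10,1,1,100
b,toy_lowdens,41,10,1,1,100
b,toy_lowdens,42,10,1,1,100
b,toy_lowdens,43,10,1,1,100
b,toy_lowdens,44,10,1,1,100
b,toy_lowdens,45,10,1,1,100
b,toy_lowdens,46,10,1,1,100
b,toy_lowdens,47,10,1,1,100
b,toy_lowdens,48,10,1,1,100
b,toy_lowdens,49,10,1,1,100
b,toy_lowdens,50,10,1,1,100
b,toy_lowdens,51,10,1,0,0
b,toy_lowdens,52,10,1,0,0
b,toy_lowdens,53,10,1,0,0
b,toy_lowdens,54,10,1,0,0
b,toy_lowdens,55,10,1,0,0
b,toy_lowdens,56,10,1,0,0
b,toy_lowdens,57,10,1,0,0
b,toy_lowdens,58,10,1,0,0
b,toy_lowdens,59,10,1,0,0
b,toy_lowdens,60,10,1,0,0
b,toy_lowdens,61,10,1,0,0
b,toy_lowdens,62,10,1,0,0
b,toy_lowdens,63,10,1,0,0
b,toy_lowdens,64,10,1,0,0
b,toy_lowdens,65,10,1,0,0
b,toy_lowdens,66,10,1,0,0
b,toy_lowdens,67,10,1,0,0
b,toy_lowdens,68,10,1,0,0
b,toy_lowdens,69,10,1,0,0
b,toy_lowdens,70,10,1,0,0
b,toy_lowdens,71,10,1,0,0
b,toy_lowdens,72,10,1,0,0
b,toy_lowdens,73,10,1,0,0
b,toy_lowdens,74,10,1,0,0
b,toy_lowdens,75,10,1,0,0
b,toy_lowdens,76,10,1,0,0
b,toy_lowdens,77,10,1,0,0
b,toy_lowdens,78,10,1,0,0
b,toy_lowdens,79,10,1,0,0
b,toy_lowdens,80,10,1,0,0
b,toy_lowdens,81,10,1,0,0
b,toy_lowdens,82,10,1,0,0
b,toy_lowdens,83,10,1,0,0
b,toy_lowdens,84,10,1,0,0
b,toy_lowdens,85,10,1,0,0
b,toy_lowdens,86,10,1,0,0
b,toy_lowdens,87,10,1,0,0
b,toy_lowdens,88,10,1,0,0
b,toy_lowdens,89,10,1,0,0
b,toy_lowdens,90,10,1,0,0
b,toy_lowdens,91,10,1,0,0
b,toy_lowdens,92,10,1,0,0
b,toy_lowdens,93,10,1,0,0
b,toy_lowdens,94,10,1,0,0
b,toy_lowdens,95,10,1,0,0
b,toy_lowdens,96,10,1,0,0
b,toy_lowdens,97,10,1,0,0
b,toy_lowdens,98,10,1,0,0
b,toy_lowdens,99,10,1,0,0
b,toy_lowdens,100,10,1,0,0
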