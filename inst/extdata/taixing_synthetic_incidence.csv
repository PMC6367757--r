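age_start,age_end,rate_per_100k
25,29,3
30,34,8
35,39,15
40,44,25
45,49,35
50,54,45
55,59,52
60,64,55
65,69,50
70,74,45
75,79,40
80,84,35
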