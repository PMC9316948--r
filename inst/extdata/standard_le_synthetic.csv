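age_start,std_le
0,85.3109
5,80.3234
10,75.3417
15,70.3685
20,65.4078
25,60.4649
30,55.5475
35,50.666
40,45.8349
45,41.0735
50,36.4071
55,31.8681
60,27.4968
65,23.3414
70,19.4568
75,15.903
80,12.7422
85,10.0399
90,7.8811
95,6.4515
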