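process_id,cycle_time_s,sec_ge60,sec_ge90,sec_ge135,sec_ge180
1,70,30,24,14,2
2,66,26,21,12,1
3,75,29,24,15,2
4,62,23,18,11,1
5,68,26,20,12,1
6,72,27,22,13,2
7,64,23,19,11,1
8,77,29,23,14,2
9,70,25,20,12,1
10,66,25,16,6,0
11,73,28,17,7,1
12,62,24,15,5,0
13,70,27,17,6,0
14,75,28,18,7,1
15,64,24,15,6,0
16,69,26,16,6,0
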