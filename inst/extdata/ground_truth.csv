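test_number,sf_gt,ef_gt,actions_gt
1,171,500,5
2,149,500,7
3,220,500,5
4,186,500,5
5,225,500,6
6,171,500,6
7,100,500,5
8,1,500,5
9,84,500,6
10,130,500,4
11,180,500,4
12,93,500,5
13,138,500,5
14,145,500,7
15,153,500,5
16,147,500,5
17,207,500,5
18,165,472,4
19,113,500,7
20,153,500,7
21,218,7011,15
22,7376,20023,32
23,403,5390,12
24,165,5390,15
25,6019,8052,11
26,56,3599,19
27,1,3899,19
28,270,2639,13
29,295,5400,16
30,405,5381,18
31,158,5224,18
32,6015,8048,11
33,1,3599,14
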