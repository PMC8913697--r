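# id type x y z radius parent
1 3 0.000000000 0.000000000 0 2.000000000 -1
2 3 5.000000000 0.000000000 0 2.000000000 1
3 3 10.000000000 0.000000000 0 2.000000000 2
4 3 15.000000000 0.000000000 0 2.000000000 3
5 3 20.000000000 0.000000000 0 2.000000000 4
6 3 25.000000000 0.000000000 0 2.000000000 5
7 3 30.000000000 0.000000000 0 2.000000000 6
8 3 35.000000000 0.000000000 0 2.000000000 7
9 3 40.000000000 0.000000000 0 2.000000000 8
10 3 44.330127019 2.500000000 0 2.000000000 9
11 3 48.660254038 5.000000000 0 2.000000000 10
12 3 52.990381057 7.500000000 0 2.000000000 11
13 3 57.320508076 10.000000000 0 2.000000000 12
14 3 61.650635095 12.500000000 0 2.000000000 13
15 3 65.980762114 15.000000000 0 2.000000000 14
16 3 44.330127019 -2.500000000 0 2.000000000 9
17 3 48.660254038 -5.000000000 0 2.000000000 16
18 3 52.990381057 -7.500000000 0 2.000000000 17
19 3 57.320508076 -10.000000000 0 2.000000000 18
20 3 61.650635095 -12.500000000 0 2.000000000 19
21 3 65.980762114 -15.000000000 0 2.000000000 20
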