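"cycle","age","rate"
1,62,0.0205506729
2,63,0.0227294896
3,64,0.0251393082
4,65,0.0278046197
5,66,0.0307525121
6,67,0.0340129449
7,68,0.0376190543
8,69,0.0416074894
9,70,0.0460187851
10,71,0.0508977737
11,72,0.056294041
12,73,0.0622624294
13,74,0.0688635965
14,75,0.0761646303
15,76,0.084239732
16,77,0.0931709694
17,78,0.1030491116
18,79,0.113974551
19,80,0.1260583237
20,81,0.1394232383
21,82,0.1542051235
22,83,0.1654
23,84,0.1654
24,85,0.1654
25,86,0.1654
26,87,0.1654
27,88,0.1654
28,89,0.1654
29,90,0.1654
30,91,0.1654
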