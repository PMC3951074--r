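age,qx
0,0.00021497688915628199
1,0.000216554112543621
2,0.00021829721106814137
3,0.00022022362932938577
4,0.00022235264644987485
5,0.00022470556898146476
6,0.00022730594409425819
7,0.00023017979517714338
8,0.00023335588220696479
9,0.00023686598948824411
10,0.000240745243638818
11,0.00024503246499985032
12,0.00024977055598074394
13,0.00025500693021840437
14,0.00026079398683720445
15,0.00026718963454519518
16,0.00027425787079837782
17,0.00028206942181419059
18,0.00029070244981832527
19,0.00030024333458023023
20,0.00031078753702884487
21,0.00032244055355601375
22,0.00033531897051475301
23,0.00034955162941086027
24,0.0003652809143854796
25,0.00038266417479182468
26,0.00040187529700652647
27,0.00042310644108678463
28,0.00044656995950642653
29,0.00047250051699687656
30,0.00050115743248924094
31,0.00053282726632952748
32,0.00056782667833477074
33,0.00060650558489627748
34,0.00064925064624021811
35,0.00069648911815400893
36,0.00074869310600189642
37,0.00080638426272039432
38,0.00087013897673049456
39,0.00094059410036972935
40,0.0010184532745625141
41,0.0011044939110617102
42,0.0011995748997376543
43,0.0013046451151190741
44,0.001420752803741987
45,0.001549055941886035
46,0.0016908336620280462
47,0.0018474988558606631
48,0.0020206120720663856
49,0.0022118968382418558
50,0.0024232565484914037
51,0.0026567930712694254
52,0.0029148272460989277
53,0.0031999214528283249
54,0.0035149044531143092
55,0.0038628987208197962
56,0.0042473504959221753
57,0.0046720628152714383
58,0.0051412317929500073
59,0.0056594864428897163
60,0.006231932356496217
61,0.0068641995679400436
62,0.0075624949589909729
63,0.0083336595731405838
64,0.0091852312244281586
65,0.010125512798775493
66,0.011163646653396642
67,0.012309695521264152
68,0.013574730320577433
69,0.014970925251068135
70,0.016511660526592364
71,0.018211633042867548
72,0.020086975205666602
73,0.022155382042535976
74,0.024436246583260157
75,0.026950803312653759
76,0.029722279264067453
77,0.032776052021828095
78,0.036139813522344411
79,0.039843738071402401
80,0.043920652411669314
81,0.048406204959818511
82,0.053339030465047843
83,0.058760905296317278
84,0.064716887319310579
85,0.071255432850558464
86,0.078428481451158105
87,0.086291497325310829
88,0.094903453805371241
89,0.10432674483219917
90,0.11462700449140606
91,0.12587281258173322
92,0.13813526094569739
93,0.15148735200744023
94,0.1660031978249763
95,0.18175698524285322
96,0.19882167079941981
97,0.21726736839938476
98,0.23715939405428921
99,0.25855593603412852
100,0.28150532655057847
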