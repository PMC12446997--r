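age,sex,rate_all_cause,rate_mi,rate_stroke
19,male,0.00028147,1.407e-05,8.44e-06
20,male,0.00030659,1.533e-05,9.2e-06
21,male,0.00033396,1.67e-05,1.002e-05
22,male,0.00036377,1.819e-05,1.091e-05
23,male,0.00039624,1.981e-05,1.189e-05
24,male,0.0004316,2.158e-05,1.295e-05
25,male,0.00047013,2.351e-05,1.41e-05
26,male,0.0005121,2.56e-05,1.536e-05
27,male,0.00055781,2.789e-05,1.673e-05
28,male,0.0006076,3.038e-05,1.823e-05
29,male,0.00066183,3.309e-05,1.985e-05
30,male,0.00072091,3.605e-05,2.163e-05
31,male,0.00078526,3.926e-05,2.356e-05
32,male,0.00085535,4.277e-05,2.566e-05
33,male,0.0009317,4.658e-05,2.795e-05
34,male,0.00101486,5.074e-05,3.045e-05
35,male,0.00110545,5.527e-05,3.316e-05
36,male,0.00120413,6.021e-05,3.612e-05
37,male,0.00131161,6.558e-05,3.935e-05
38,male,0.00142869,7.143e-05,4.286e-05
39,male,0.00155621,7.781e-05,4.669e-05
40,male,0.00169512,8.476e-05,5.085e-05
41,male,0.00184643,9.232e-05,5.539e-05
42,male,0.00201125,0.00010056,6.034e-05
43,male,0.00219077,0.00010954,6.572e-05
44,male,0.00238633,0.00011932,7.159e-05
45,male,0.00259933,0.00012997,7.798e-05
46,male,0.00283135,0.00014157,8.494e-05
47,male,0.00308409,0.0001542,9.252e-05
48,male,0.00335938,0.00016797,0.00010078
49,male,0.00365924,0.00018296,0.00010978
50,male,0.00398587,0.00019929,0.00011958
51,male,0.00434165,0.00021708,0.00013025
52,male,0.0047292,0.00023646,0.00014188
53,male,0.00515133,0.00025757,0.00015454
54,male,0.00561115,0.00028056,0.00016833
55,male,0.00611201,0.0003056,0.00018336
56,male,0.00665757,0.00033288,0.00019973
57,male,0.00725184,0.00036259,0.00021756
58,male,0.00789915,0.00039496,0.00023697
59,male,0.00860424,0.00043021,0.00025813
60,male,0.00937227,0.00046861,0.00028117
61,male,0.01020885,0.00051044,0.00030627
62,male,0.01112011,0.00055601,0.0003336
63,male,0.01211271,0.00060564,0.00036338
64,male,0.01319391,0.0006597,0.00039582
65,male,0.01437162,0.00071858,0.00043115
66,male,0.01565445,0.00078272,0.00046963
67,male,0.01705179,0.00085259,0.00051155
68,male,0.01857386,0.00092869,0.00055722
69,male,0.02023179,0.00101159,0.00060695
70,male,0.02203771,0.00110189,0.00066113
71,male,0.02400484,0.00120024,0.00072015
72,male,0.02614754,0.00130738,0.00078443
73,male,0.02848151,0.00142408,0.00085445
74,male,0.03102382,0.00155119,0.00093071
75,male,0.03379305,0.00168965,0.00101379
76,male,0.03680947,0.00184047,0.00110428
77,male,0.04009515,0.00200476,0.00120285
78,male,0.0436741,0.00218371,0.00131022
79,male,0.04757252,0.00237863,0.00142718
80,male,0.05181892,0.00259095,0.00155457
81,male,0.05644435,0.00282222,0.00169333
82,male,0.06148267,0.00307413,0.00184448
83,male,0.0669707,0.00334854,0.00200912
84,male,0.07294861,0.00364743,0.00218846
85,male,0.07946012,0.00397301,0.0023838
19,female,0.00017733,8.87e-06,5.32e-06
20,female,0.00019355,9.68e-06,5.81e-06
21,female,0.00021124,1.056e-05,6.34e-06
22,female,0.00023056,1.153e-05,6.92e-06
23,female,0.00025164,1.258e-05,7.55e-06
24,female,0.00027465,1.373e-05,8.24e-06
25,female,0.00029977,1.499e-05,8.99e-06
26,female,0.00032718,1.636e-05,9.82e-06
27,female,0.0003571,1.785e-05,1.071e-05
28,female,0.00038975,1.949e-05,1.169e-05
29,female,0.00042539,2.127e-05,1.276e-05
30,female,0.00046429,2.321e-05,1.393e-05
31,female,0.00050675,2.534e-05,1.52e-05
32,female,0.00055308,2.765e-05,1.659e-05
33,female,0.00060366,3.018e-05,1.811e-05
34,female,0.00065886,3.294e-05,1.977e-05
35,female,0.00071911,3.596e-05,2.157e-05
36,female,0.00078486,3.924e-05,2.355e-05
37,female,0.00085663,4.283e-05,2.57e-05
38,female,0.00093497,4.675e-05,2.805e-05
39,female,0.00102046,5.102e-05,3.061e-05
40,female,0.00111378,5.569e-05,3.341e-05
41,female,0.00121562,6.078e-05,3.647e-05
42,female,0.00132678,6.634e-05,3.98e-05
43,female,0.0014481,7.241e-05,4.344e-05
44,female,0.00158052,7.903e-05,4.742e-05
45,female,0.00172505,8.625e-05,5.175e-05
46,female,0.00188279,9.414e-05,5.648e-05
47,female,0.00205496,0.00010275,6.165e-05
48,female,0.00224287,0.00011214,6.729e-05
49,female,0.00244796,0.0001224,7.344e-05
50,female,0.00267181,0.00013359,8.015e-05
51,female,0.00291612,0.00014581,8.748e-05
52,female,0.00318278,0.00015914,9.548e-05
53,female,0.00347382,0.00017369,0.00010421
54,female,0.00379148,0.00018957,0.00011374
55,female,0.00413818,0.00020691,0.00012415
56,female,0.00451658,0.00022583,0.0001355
57,female,0.00492959,0.00024648,0.00014789
58,female,0.00538036,0.00026902,0.00016141
59,female,0.00587235,0.00029362,0.00017617
60,female,0.00640933,0.00032047,0.00019228
61,female,0.00699542,0.00034977,0.00020986
62,female,0.00763509,0.00038175,0.00022905
63,female,0.00833326,0.00041666,0.00025
64,female,0.00909528,0.00045476,0.00027286
65,female,0.00992697,0.00049635,0.00029781
66,female,0.01083471,0.00054174,0.00032504
67,female,0.01182547,0.00059127,0.00035476
68,female,0.01290681,0.00064534,0.0003872
69,female,0.01408704,0.00070435,0.00042261
70,female,0.01537519,0.00076876,0.00046126
71,female,0.01678113,0.00083906,0.00050343
72,female,0.01831564,0.00091578,0.00054947
73,female,0.01999046,0.00099952,0.00059971
74,female,0.02181844,0.00109092,0.00065455
75,female,0.02381356,0.00119068,0.00071441
76,female,0.02599113,0.00129956,0.00077973
77,female,0.02836782,0.00141839,0.00085103
78,female,0.03096183,0.00154809,0.00092886
79,female,0.03379305,0.00168965,0.00101379
80,female,0.03688317,0.00184416,0.0011065
81,female,0.04025585,0.00201279,0.00120768
82,female,0.04393693,0.00219685,0.00131811
83,female,0.04795463,0.00239773,0.00143864
84,female,0.05233971,0.00261699,0.00157019
85,female,0.05712577,0.00285629,0.00171377
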