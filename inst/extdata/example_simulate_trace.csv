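# ramkin 0.1.0
# seed: 7
# config: c181a1d0233f33aab2d43ddfc612db7a
# units: concentrations nM, time s, potential mV, uptake nmol/mg
time_s,ca_nM,RO,cumulative_uptake_nmol_per_mg
0,50,0.9998963649,0
0,209,0.9998963649,0
0.2083333333,209,0.03812254872,0.3315130356
0.4166666667,209,0.003567626683,0.3459240099
0.625,209,0.002326126221,0.3489420383
0.8333333333,209,0.002281521189,0.3515507373
1.041666667,209,0.002279918605,0.3541447298
1.25,209,0.002279861027,0.3567381939
1.458333333,209,0.002279858958,0.359331639
1.666666667,209,0.002279858884,0.3619250835
1.875,209,0.002279858881,0.3645185279
2.083333333,209,0.002279858881,0.3671119723
2.291666667,209,0.002279858881,0.3697054167
2.5,209,0.002279858881,0.3722988611
2.708333333,209,0.002279858881,0.3748923055
2.916666667,209,0.002279858881,0.3774857499
3.125,209,0.002279858881,0.3800791944
3.333333333,209,0.002279858881,0.3826726388
3.541666667,209,0.002279858881,0.3852660832
3.75,209,0.002279858881,0.3878595276
3.958333333,209,0.002279858881,0.390452972
4.166666667,209,0.002279858881,0.3930464164
4.375,209,0.002279858881,0.3956398608
4.583333333,209,0.002279858881,0.3982333052
4.791666667,209,0.002279858881,0.4008267496
5,209,0.002279858881,0.403420194
5,98,0.002279858881,0.403420194
6.25,98,0.04889919543,0.4034201956
7.5,98,0.09333996238,0.4034202
8.75,98,0.1357039665,0.4034202069
10,98,0.1760882571,0.4034202164
11.25,98,0.2145853483,0.4034202284
12.5,98,0.2512834307,0.4034202425
13.75,98,0.2862665739,0.4034202589
15,98,0.3196149189,0.4034202774
16.25,98,0.3514048613,0.4034202978
17.5,98,0.381709227,0.4034203201
18.75,98,0.4105974385,0.4034203443
20,98,0.4381356741,0.4034203701
21.25,98,0.4643870196,0.4034203976
22.5,98,0.4894116127,0.4034204266
23.75,98,0.5132667808,0.4034204572
25,98,0.5360071724,0.4034204891
26.25,98,0.557684882,0.4034205224
27.5,98,0.5783495699,0.403420557
28.75,98,0.5980485757,0.4034205929
30,98,0.6168270267,0.4034206298
31.25,98,0.6347279413,0.403420668
32.5,98,0.6517923277,0.4034207071
33.75,98,0.6680592778,0.4034207473
35,98,0.6835660566,0.4034207885
35,209,0.6835660566,0.4034207885
35.20833333,209,0.02675733067,0.6306379999
35.41666667,209,0.003159293438,0.6413018
35.625,209,0.002311455492,0.6441851987
35.83333333,209,0.002280994095,0.6467890607
36.04166667,209,0.002279899668,0.6493828794
36.25,209,0.002279860347,0.6519763373
36.45833333,209,0.002279858934,0.6545697822
36.66666667,209,0.002279858883,0.6571632266
36.875,209,0.002279858881,0.659756671
37.08333333,209,0.002279858881,0.6623501154
37.29166667,209,0.002279858881,0.6649435598
37.5,209,0.002279858881,0.6675370042
37.70833333,209,0.002279858881,0.6701304486
37.91666667,209,0.002279858881,0.6727238931
38.125,209,0.002279858881,0.6753173375
38.33333333,209,0.002279858881,0.6779107819
38.54166667,209,0.002279858881,0.6805042263
38.75,209,0.002279858881,0.6830976707
38.95833333,209,0.002279858881,0.6856911151
39.16666667,209,0.002279858881,0.6882845595
39.375,209,0.002279858881,0.6908780039
39.58333333,209,0.002279858881,0.6934714483
39.79166667,209,0.002279858881,0.6960648927
40,209,0.002279858881,0.6986583372
40,50,0.002279858881,0.6986583372
40.41666667,50,0.0181163345,0.6986583372
40.83333333,50,0.03370141697,0.6986583372
41.25,50,0.04903909698,0.6986583372
41.66666667,50,0.06413330187,0.6986583372
42.08333333,50,0.07898789664,0.6986583372
42.5,50,0.09360668495,0.6986583372
42.91666667,50,0.10799341,0.6986583372
43.33333333,50,0.1221517558,0.6986583372
43.75,50,0.1360853475,0.6986583372
44.16666667,50,0.1497977531,0.6986583372
44.58333333,50,0.1632924836,0.6986583372
45,50,0.1765729946,0.6986583372
45.41666667,50,0.1896426866,0.6986583372
45.83333333,50,0.2025049063,0.6986583372
46.25,50,0.215162947,0.6986583372
46.66666667,50,0.2276200501,0.6986583372
47.08333333,50,0.2398794052,0.6986583372
47.5,50,0.2519441515,0.6986583372
47.91666667,50,0.2638173783,0.6986583372
48.33333333,50,0.2755021258,0.6986583372
48.75,50,0.2870013859,0.6986583372
49.16666667,50,0.2983181032,0.6986583372
49.58333333,50,0.3094551754,0.6986583372
50,50,0.3204154542,0.6986583372
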