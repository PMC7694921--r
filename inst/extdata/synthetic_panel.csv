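city,year,region,population_thousand,area_km2,institutions,beds,health_workers,gov_subsidy_bn,total_expenditure_bn,outpatient_10k,hosp_rate_pct,general_income_bn
Changzhou,2014,south,2868.4908,7080.2849,1027.7261,24562.09,35002.335,2.4598384,12.079488,2540.6442,14.331124,13.02428
Huaian,2014,north,8150.8337,10416.661,3396.6914,38158.945,44060.367,1.7440777,14.700229,4244.1495,16.073498,13.072127
Lianyungang,2014,north,2842.8935,13399.205,1233.8568,11955.403,21448.381,0.60962583,5.0316814,1249.3675,14.709266,5.3367438
Nanjing,2014,south,5546.8025,8522.2818,1866.3795,43896.539,85264.144,3.5386651,27.468336,4095.9722,17.707635,21.441662
Nantong,2014,middle,3683.5918,6904.2666,1306.8791,24133.489,32477.602,1.2739219,11.208152,1847.4461,15.263269,8.3186255
Suqian,2014,north,7683.3634,13875.962,3262.4845,36648.688,54849.714,1.4111888,16.995852,4435.6562,14.454327,17.495372
Suzhou,2014,south,8236.52,4812.8314,3035.0657,52622.421,99273.079,6.6227719,30.83073,8724.0835,13.408914,33.193399
Taizhou,2014,middle,3208.6283,7161.179,1194.142,15000.961,24185.483,1.0537664,7.5938365,1689.8787,15.563755,9.1561445
Wuxi,2014,south,7666.0527,6966.8982,3359.5672,68674.761,106488.72,3.9026416,54.394977,7758.416,14.355299,34.288133
Xuzhou,2014,north,8050.6466,6833.298,3393.1948,30555.722,42376.718,1.6934069,19.150064,4699.6863,17.115128,9.6501774
Yancheng,2014,north,6642.0147,7168.7696,3303.7768,27149.53,43757.515,0.98601339,9.327327,3455.3828,15.984888,10.013295
Yangzhou,2014,middle,7971.0906,8284.5504,3425.6325,50776.732,89410.341,2.7563696,18.588594,5933.8527,16.828777,18.169955
Zhenjiang,2014,south,10528.373,8589.041,4638.7879,81258.389,100856.7,5.6605646,50.608808,8788.5664,16.682426,45.524488
Changzhou,2015,south,2868.4908,7080.2849,1002.2852,26224.446,36917.058,2.8718701,13.724456,2591.5635,14.585776,15.383199
Huaian,2015,north,8150.8337,10416.661,3400.7673,39621.145,46353.307,2.1128634,16.723026,4639.5343,16.484014,14.344253
Lianyungang,2015,north,2842.8935,13399.205,1262.9153,12993.073,21912.24,0.67450652,5.5773435,1330.8963,14.506698,5.9842334
Nanjing,2015,south,5546.8025,8522.2818,1891.6659,46335.369,89714.717,4.1280282,31.137628,4356.4404,17.870679,23.637437
Nantong,2015,middle,3683.5918,6904.2666,1347.0021,26174.123,34693.782,1.4861037,12.674186,1908.7364,16.310903,8.7941271
Suqian,2015,north,7683.3634,13875.962,3340.7921,39992.609,58218.797,1.6241736,18.957844,4834.7496,14.278549,19.435492
Suzhou,2015,south,8236.52,4812.8314,3078.3179,55553.909,105984.39,7.8975301,34.593026,9067.3583,13.717635,35.810095
Taizhou,2015,middle,3208.6283,7161.179,1252.9645,16158.544,25519.133,1.2641544,9.1728917,1872.3086,15.557428,10.417402
Wuxi,2015,south,7666.0527,6966.8982,3256.904,73182.468,102032.23,4.754581,60.542263,8156.9078,15.275125,38.28233
Xuzhou,2015,north,8050.6466,6833.298,3494.9394,30847.882,43995.031,2.0245002,20.239874,4890.4905,16.688213,11.074741
Yancheng,2015,north,6642.0147,7168.7696,3201.3202,27775.023,45980.799,1.1002394,10.376408,3604.0439,15.259296,10.74489
Yangzhou,2015,middle,7971.0906,8284.5504,3465.2413,56421.108,91320.434,3.1979061,20.213048,6102.6906,17.204892,20.511192
Zhenjiang,2015,south,10528.373,8589.041,4760.5341,87068.757,103984.19,6.4850844,53.581757,8723.9709,17.013286,51.366685
Changzhou,2016,south,2868.4908,7080.2849,993.43666,27940.824,41502.789,3.3348677,15.653016,2880.5179,14.604549,17.138525
Huaian,2016,north,8150.8337,10416.661,3404.6008,41982.35,48853.072,2.3821011,18.489094,4690.797,16.457599,15.508216
Lianyungang,2016,north,2842.8935,13399.205,1284.7722,13343.746,23136.788,0.77687883,6.2399229,1405.5611,14.113339,6.9002004
Nanjing,2016,south,5546.8025,8522.2818,1909.4452,50294.907,97765.283,4.8777342,35.690657,4578.6541,17.792595,25.987695
Nantong,2016,middle,3683.5918,6904.2666,1309.0445,27266.214,35703.682,1.7033716,13.673945,2082.5414,16.535426,10.012226
Suqian,2016,north,7683.3634,13875.962,3371.1374,42880.264,61845.287,1.8692575,21.068664,4957.3888,14.258138,21.036022
Suzhou,2016,south,8236.52,4812.8314,3121.6779,56261.743,110592.91,9.2912912,39.007097,9713.6347,13.585184,39.044624
Taizhou,2016,middle,3208.6283,7161.179,1242.0744,17470.096,27777.145,1.4108519,9.7373392,1956.0032,15.18334,11.609291
Wuxi,2016,south,7666.0527,6966.8982,3271.5723,77215.806,109387.82,5.3016786,67.868732,8660.034,14.703991,42.289054
Xuzhou,2016,north,8050.6466,6833.298,3401.8723,32678.035,48290.095,2.2685829,23.603999,5174.6748,17.066229,12.23193
Yancheng,2016,north,6642.0147,7168.7696,3296.6314,30327.909,49216.431,1.2775642,11.563405,3822.6397,15.702174,11.96268
Yangzhou,2016,middle,7971.0906,8284.5504,3481.3122,56337.826,98575.774,3.7210099,21.654267,6386.456,17.21939,23.221866
Zhenjiang,2016,south,10528.373,8589.041,4601.559,94266.771,108315.3,7.5358881,60.161789,9287.9776,17.442967,56.65827
Changzhou,2017,south,2868.4908,7080.2849,1040.6341,29494.884,42649.242,3.856097,17.423767,2991.7325,13.978272,18.114386
Huaian,2017,north,8150.8337,10416.661,3437.9463,44811.113,50213.967,2.8469212,20.653769,4706.0834,16.447434,16.985807
Lianyungang,2017,north,2842.8935,13399.205,1215.3224,14256.398,24494.507,0.9154193,6.9874836,1454.8782,14.165524,7.5284982
Nanjing,2017,south,5546.8025,8522.2818,1936.1727,53308.553,102861.76,5.4841962,39.40186,4874.9912,17.567927,29.288704
Nantong,2017,middle,3683.5918,6904.2666,1318.3702,27411.762,39086.606,2.0657801,15.319006,2123.9951,15.96704,10.794203
Suqian,2017,north,7683.3634,13875.962,3383.2693,44324.718,66499.111,2.1716434,23.228688,5284.4517,13.701299,23.869322
Suzhou,2017,south,8236.52,4812.8314,3269.1866,60952.18,112369,10.821027,44.881939,10171.868,13.477329,45.933414
Taizhou,2017,middle,3208.6283,7161.179,1255.4775,17432.145,27069.155,1.6261543,10.992712,1996.7383,15.607745,12.40198
Wuxi,2017,south,7666.0527,6966.8982,3200.6923,81006.017,120995.13,6.1753034,76.492818,9018.3801,15.33303,47.534861
Xuzhou,2017,north,8050.6466,6833.298,3427.0156,33885.325,51499.393,2.7437047,27.121236,5124.2808,17.513375,13.760877
Yancheng,2017,north,6642.0147,7168.7696,3319.6672,31992.455,51539.084,1.5212214,13.378229,3905.6358,15.899639,13.364683
Yangzhou,2017,middle,7971.0906,8284.5504,3576.1611,60722.765,104250.7,4.4358547,25.834449,6442.7391,16.925658,24.758122
Zhenjiang,2017,south,10528.373,8589.041,4660.7945,95570.111,112661.88,8.8504139,69.504416,10105.411,16.565225,63.884803
Changzhou,2018,south,2868.4908,7080.2849,1018.5731,30881.185,43288.962,4.5945793,18.929803,3034.5,14.250436,20.797997
Huaian,2018,north,8150.8337,10416.661,3359.5738,46526.929,54306.181,3.2341469,23.499782,5155.712,16.481609,19.220642
Lianyungang,2018,north,2842.8935,13399.205,1290.3167,14824.37,26192.342,1.1136942,7.8158216,1655.9893,14.198649,8.5059262
Nanjing,2018,south,5546.8025,8522.2818,2011.0365,57028.444,105908.57,6.3923934,44.497694,4908.9966,17.707316,31.275683
Nantong,2018,middle,3683.5918,6904.2666,1345.8057,29210.295,40827.441,2.3372757,17.143536,2218.8069,16.017165,11.968015
Suqian,2018,north,7683.3634,13875.962,3426.5542,45042.095,69311.051,2.6325715,26.123496,5550.197,14.621868,27.12986
Suzhou,2018,south,8236.52,4812.8314,3101.5041,63358.123,126689.14,13.012897,50.962174,10441.749,13.487813,49.576491
Taizhou,2018,middle,3208.6283,7161.179,1281.9483,18368.103,30453.428,1.9978689,12.47141,2081.1755,14.810203,13.459813
Wuxi,2018,south,7666.0527,6966.8982,3251.6876,82187.531,125751.22,7.3512055,85.401879,9362.1373,15.000128,50.564932
Xuzhou,2018,north,8050.6466,6833.298,3443.3107,36630.5,53505.295,3.2074047,29.653171,5547.94,16.512394,14.994212
Yancheng,2018,north,6642.0147,7168.7696,3356.8914,32624.408,54578.518,1.7953441,14.44552,4187.6822,15.083865,14.858742
Yangzhou,2018,middle,7971.0906,8284.5504,3462.6315,62996.879,108655.49,5.0914924,28.749116,7032.8749,16.989117,28.431559
Zhenjiang,2018,south,10528.373,8589.041,4824.0247,104362.86,118247.24,10.120688,79.094862,10411.164,17.324202,68.813344
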