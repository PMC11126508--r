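age_from,age_to,n,from,to,estimate,ci_low,ci_high
3,5,10399,underweight,underweight,0.7228,0.4704,0.8699
3,5,10399,underweight,healthy,0.2719,0.1283,0.5155
3,5,10399,underweight,overweight,0.0051,0.0018,0.0133
3,5,10399,underweight,obesity,2e-04,0,8e-04
3,5,10399,healthy,underweight,0.0024,0.001,0.0052
3,5,10399,healthy,healthy,0.9624,0.9496,0.9719
3,5,10399,healthy,overweight,0.0332,0.0261,0.0414
3,5,10399,healthy,obesity,0.002,0.001,0.0038
3,5,10399,overweight,underweight,3e-04,1e-04,8e-04
3,5,10399,overweight,healthy,0.1928,0.1534,0.2381
3,5,10399,overweight,overweight,0.7132,0.6343,0.779
3,5,10399,overweight,obesity,0.0937,0.0675,0.1268
3,5,10399,obesity,underweight,0,0,1e-04
3,5,10399,obesity,healthy,0.0178,0.0101,0.0309
3,5,10399,obesity,overweight,0.1419,0.1079,0.1817
3,5,10399,obesity,obesity,0.8403,0.7873,0.882
5,7,10729,underweight,underweight,0.7224,0.3939,0.8931
5,7,10729,underweight,healthy,0.2733,0.1057,0.5929
5,7,10729,underweight,overweight,0.0041,0.0012,0.0124
5,7,10729,underweight,obesity,2e-04,0,8e-04
5,7,10729,healthy,underweight,0.0039,0.0018,0.0073
5,7,10729,healthy,healthy,0.9677,0.9566,0.9761
5,7,10729,healthy,overweight,0.0267,0.0212,0.0331
5,7,10729,healthy,obesity,0.0017,9e-04,0.003
5,7,10729,overweight,underweight,4e-04,1e-04,0.001
5,7,10729,overweight,healthy,0.1736,0.1392,0.2133
5,7,10729,overweight,overweight,0.7281,0.6545,0.7893
5,7,10729,overweight,obesity,0.0979,0.0714,0.1312
5,7,10729,obesity,underweight,0,0,1e-04
5,7,10729,obesity,healthy,0.0097,0.0051,0.0177
5,7,10729,obesity,overweight,0.0874,0.0616,0.1214
5,7,10729,obesity,obesity,0.9029,0.8608,0.9333
7,11,9685,underweight,underweight,0.9326,0.8339,0.9735
7,11,9685,underweight,healthy,0.0669,0.0263,0.1645
7,11,9685,underweight,overweight,5e-04,2e-04,0.0016
7,11,9685,underweight,obesity,0,0,0
7,11,9685,healthy,underweight,0.0014,6e-04,0.003
7,11,9685,healthy,healthy,0.9836,0.9785,0.9873
7,11,9685,healthy,overweight,0.0146,0.0119,0.0178
7,11,9685,healthy,obesity,4e-04,2e-04,7e-04
7,11,9685,overweight,underweight,0,0,1e-04
7,11,9685,overweight,healthy,0.0253,0.0155,0.0408
7,11,9685,overweight,overweight,0.9223,0.8911,0.9444
7,11,9685,overweight,obesity,0.0524,0.0401,0.068
7,11,9685,obesity,underweight,0,0,0
7,11,9685,obesity,healthy,2e-04,1e-04,6e-04
7,11,9685,obesity,overweight,0.0168,0.0097,0.0287
7,11,9685,obesity,obesity,0.983,0.9707,0.9902
11,14,8593,underweight,underweight,0.9042,0.7654,0.9628
11,14,8593,underweight,healthy,0.0949,0.0369,0.2316
11,14,8593,underweight,overweight,9e-04,3e-04,0.0029
11,14,8593,underweight,obesity,0,0,1e-04
11,14,8593,healthy,underweight,0.0022,9e-04,0.0051
11,14,8593,healthy,healthy,0.9798,0.971,0.9856
11,14,8593,healthy,overweight,0.0175,0.0133,0.0229
11,14,8593,healthy,obesity,5e-04,2e-04,0.001
11,14,8593,overweight,underweight,2e-04,0,3e-04
11,14,8593,overweight,healthy,0.0758,0.055,0.1034
11,14,8593,overweight,overweight,0.8716,0.8185,0.9101
11,14,8593,overweight,obesity,0.0524,0.0349,0.0778
11,14,8593,obesity,underweight,0,0,0
11,14,8593,obesity,healthy,0.0016,8e-04,0.0033
11,14,8593,obesity,overweight,0.0382,0.0258,0.0556
11,14,8593,obesity,obesity,0.9602,0.9411,0.9734
14,17,7085,underweight,underweight,0.9186,0.8185,0.9648
14,17,7085,underweight,healthy,0.0806,0.035,0.1789
14,17,7085,underweight,overweight,8e-04,2e-04,0.0025
14,17,7085,underweight,obesity,0,0,1e-04
14,17,7085,healthy,underweight,0.0023,6e-04,0.0079
14,17,7085,healthy,healthy,0.9787,0.9654,0.9859
14,17,7085,healthy,overweight,0.0183,0.0132,0.0249
14,17,7085,healthy,obesity,7e-04,3e-04,0.0018
14,17,7085,overweight,underweight,1e-04,0,5e-04
14,17,7085,overweight,healthy,0.0787,0.0551,0.1101
14,17,7085,overweight,overweight,0.8507,0.7702,0.9043
14,17,7085,overweight,obesity,0.0705,0.0406,0.1192
14,17,7085,obesity,underweight,0,0,0
14,17,7085,obesity,healthy,0.0017,7e-04,0.0041
14,17,7085,obesity,overweight,0.0391,0.0245,0.061
14,17,7085,obesity,obesity,0.9592,0.9349,0.9748
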