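1 SNP1_1 1.645740 1645740
1 SNP1_2 1.868811 1868811
1 SNP1_3 2.050773 2050773
1 SNP1_4 2.229609 2229609
1 SNP1_5 2.929340 2929340
1 SNP1_6 3.266970 3266970
1 SNP1_7 4.054268 4054268
1 SNP1_8 4.280869 4280869
1 SNP1_9 6.823546 6823546
1 SNP1_10 6.899580 6899580
1 SNP1_11 7.097760 7097760
1 SNP1_12 8.573081 8573081
1 SNP1_13 12.630022 12630022
1 SNP1_14 13.875011 13875011
1 SNP1_15 14.134868 14134868
1 SNP1_16 14.174009 14174009
1 SNP1_17 14.808063 14808063
1 SNP1_18 15.551057 15551057
1 SNP1_19 16.692113 16692113
1 SNP1_20 17.815453 17815453
1 SNP1_21 18.041225 18041225
1 SNP1_22 18.362658 18362658
1 SNP1_23 18.610480 18610480
1 SNP1_24 19.950902 19950902
2 SNP2_1 1.974043 1974043
2 SNP2_2 2.174577 2174577
2 SNP2_3 2.337710 2337710
2 SNP2_4 4.260715 4260715
2 SNP2_5 4.396967 4396967
2 SNP2_6 4.772628 4772628
2 SNP2_7 6.134206 6134206
2 SNP2_8 7.341056 7341056
2 SNP2_9 7.485548 7485548
2 SNP2_10 9.574028 9574028
2 SNP2_11 9.597274 9597274
2 SNP2_12 9.993121 9993121
2 SNP2_13 11.289278 11289278
2 SNP2_14 12.126513 12126513
2 SNP2_15 12.218350 12218350
2 SNP2_16 13.513421 13513421
2 SNP2_17 13.666248 13666248
2 SNP2_18 14.615463 14615463
2 SNP2_19 15.667318 15667318
2 SNP2_20 16.538027 16538027
2 SNP2_21 16.910877 16910877
2 SNP2_22 17.055440 17055440
2 SNP2_23 17.659595 17659595
2 SNP2_24 18.055613 18055613
3 SNP3_1 0.002435 2435
3 SNP3_2 1.043050 1043050
3 SNP3_3 2.026921 2026921
3 SNP3_4 2.400058 2400058
3 SNP3_5 3.646229 3646229
3 SNP3_6 3.896181 3896181
3 SNP3_7 5.756553 5756553
3 SNP3_8 6.474861 6474861
3 SNP3_9 8.391464 8391464
3 SNP3_10 8.652741 8652741
3 SNP3_11 10.649381 10649381
3 SNP3_12 10.682944 10682944
3 SNP3_13 11.216164 11216164
3 SNP3_14 13.461528 13461528
3 SNP3_15 14.691074 14691074
3 SNP3_16 16.153352 16153352
3 SNP3_17 16.254689 16254689
3 SNP3_18 16.618576 16618576
3 SNP3_19 17.612362 17612362
3 SNP3_20 17.692069 17692069
3 SNP3_21 17.993368 17993368
3 SNP3_22 18.202261 18202261
3 SNP3_23 19.161948 19161948
3 SNP3_24 19.993785 19993785
4 SNP4_1 0.562457 562457
4 SNP4_2 1.466899 1466899
4 SNP4_3 1.604296 1604296
4 SNP4_4 3.834420 3834420
4 SNP4_5 6.225140 6225140
4 SNP4_6 6.556116 6556116
4 SNP4_7 7.024730 7024730
4 SNP4_8 8.196069 8196069
4 SNP4_9 8.346978 8346978
4 SNP4_10 8.838072 8838072
4 SNP4_11 10.038792 10038792
4 SNP4_12 10.364057 10364057
4 SNP4_13 11.510145 11510145
4 SNP4_14 11.639273 11639273
4 SNP4_15 12.197483 12197483
4 SNP4_16 12.208444 12208444
4 SNP4_17 12.845280 12845280
4 SNP4_18 14.699571 14699571
4 SNP4_19 15.803507 15803507
4 SNP4_20 16.039182 16039182
4 SNP4_21 17.353548 17353548
4 SNP4_22 17.393767 17393767
4 SNP4_23 18.420940 18420940
4 SNP4_24 19.950076 19950076
5 SNP5_1 0.930020 930020
5 SNP5_2 2.681234 2681234
5 SNP5_3 4.305807 4305807
5 SNP5_4 5.015403 5015403
5 SNP5_5 6.032694 6032694
5 SNP5_6 6.237419 6237419
5 SNP5_7 6.768103 6768103
5 SNP5_8 6.809921 6809921
5 SNP5_9 9.351238 9351238
5 SNP5_10 9.815655 9815655
5 SNP5_11 10.480592 10480592
5 SNP5_12 11.296984 11296984
5 SNP5_13 11.720290 11720290
5 SNP5_14 13.210702 13210702
5 SNP5_15 13.601187 13601187
5 SNP5_16 14.415442 14415442
5 SNP5_17 14.498081 14498081
5 SNP5_18 15.712978 15712978
5 SNP5_19 15.859231 15859231
5 SNP5_20 17.193559 17193559
5 SNP5_21 17.523137 17523137
5 SNP5_22 17.835565 17835565
5 SNP5_23 19.596946 19596946
5 SNP5_24 19.746618 19746618
X SNPX_1 3.793617 3793617
X SNPX_2 11.324915 11324915
X SNPX_3 12.128830 12128830
X SNPX_4 12.829150 12829150
X SNPX_5 13.106484 13106484
X SNPX_6 13.930733 13930733
Y SNPY_1 4.706771 4706771
Y SNPY_2 11.271718 11271718
0 SNP0_1 13.062399 13062399
0 SNP0_2 17.230508 17230508
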