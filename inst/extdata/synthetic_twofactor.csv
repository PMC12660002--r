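"mv1","mv2","mv3","mv4","mv5","mv6"
1.716,0.0109,0.5543,-0.1102,0.7689,0.4845
0.744,-0.1852,-0.6854,-0.1437,-1.5222,0.0664
0.2621,0.2592,0.944,-0.6097,-1.5965,0.6535
0.5743,0.4845,0.4586,0.2719,-1.1267,-0.9552
-1.7009,-0.4397,-0.4746,-1.9929,-0.5379,-1.5796
-1.4476,-1.7691,-1.7941,-1.0607,0.088,-0.0412
-0.9046,0.1769,-0.4219,-2.0731,-1.9468,-1.9768
-0.8383,-0.493,-1.478,1.683,0.6871,-0.1708
0.4707,0.3005,0.9543,-0.4984,-0.2383,-0.4935
0.3957,-0.7659,-0.7167,0.3716,0.3787,-0.2843
-0.3213,-0.0236,-0.4981,-0.7213,0.6783,0.0895
1.3494,-0.838,-0.0299,-0.326,0.0401,0.3034
0.2599,1.009,-0.4387,1.7013,1.1328,2.2254
-0.3028,-0.0011,-0.2329,0.029,-1.6372,-0.7076
-1.4887,-2.568,-0.7194,-1.1644,1.4423,0.4561
0.8816,2.0258,0.5037,-1.8553,-0.6171,-1.7393
-0.3373,0.2638,0.2755,1.0952,1.907,1.8942
0.5097,-0.6869,1.2153,-0.1519,-0.4554,-0.3524
0.1022,-1.2456,-0.8112,-0.0122,-0.6099,-1.3485
0.7584,0.5999,0.0962,1.0081,1.1762,1.5304
0.0303,-0.5116,-0.0502,-0.0292,-0.7435,-0.6199
-0.0053,0.1134,0.3171,1.3162,1.2073,1.5249
-0.3847,-1.2903,-1.4455,-1.3689,-1.921,-1.4728
0.129,0.2093,0.9387,-0.1476,-0.5233,-1.7331
0.8531,-0.1183,-0.0533,0.3877,-0.3929,0.1981
0.7064,2.5643,0.6671,1.4012,-0.316,0.3968
1.4608,1.2057,1.2374,0.8678,0.6772,1.6059
0.5897,-0.2739,1.2373,-0.7308,-0.5074,-0.5707
0.624,0.4739,1.0827,1.271,0.3869,1.2451
0.1172,2.3492,0.7041,2.8615,2.1114,1.4029
-0.3568,-0.9198,-0.1252,-2.7633,-2.746,-1.4098
0.3543,0.5668,-0.0572,1.2443,2.5145,1.8577
0.5195,-0.5494,-0.2958,-0.909,-2.0344,-0.2608
0.5891,0.099,0.8522,0.3665,0.9582,0.8904
0.5369,-0.0419,0.5575,-1.8901,-1.399,-0.6076
1.6315,1.4021,1.4792,0.1792,-0.8507,0.375
-0.0806,0.8299,0.7435,-0.6962,-0.3467,-0.3393
-1.068,-0.1567,-1.1971,-1.1636,-0.7535,0.0327
0.4023,1.0666,0.0567,-0.4652,0.4138,-0.5993
-0.3436,0.4938,-1.441,0.4311,-0.6408,1.8865
0.1755,-0.9296,-0.3801,1.063,1.6243,0.9951
-0.0617,-0.7377,1.5116,-0.0767,0.1587,0.3132
-1.4695,-1.304,-1.9978,0.2787,-1.0752,0.1137
0.7644,-0.1684,0.2731,-1.2286,-0.8613,-0.4669
-0.8737,-0.8596,-0.227,0.3488,-0.0709,1.255
0.8507,1.8171,0.8478,1.1009,-0.8251,0.8899
0.9313,0.2839,-0.0807,-0.8336,0.3667,-2.2236
-0.7192,-0.7781,-1.0013,1.7541,2.0786,0.7082
0.053,0.9386,1.4718,-0.8309,-0.5978,0.4586
0.1199,0.7406,0.1516,-0.4596,-1.673,0.2611
-1.1045,-1.112,0.0106,-0.7869,-0.8224,-1.4623
-0.6314,0.0534,-0.6059,-1.3992,-1.5542,-2.3892
-0.0387,-0.5057,0.2523,0.5244,0.0496,-0.857
-0.0224,0.5774,0.6989,0.1121,1.0464,-0.3126
-0.4076,-0.852,-0.4379,-1.5858,-0.45,-1.6099
-0.0667,0.211,0.6594,-0.2698,-0.2196,0.3185
-2.1886,-2.2768,-1.1342,-0.3257,0.3912,-0.3691
-0.4346,-0.4677,-0.9364,0.4248,1.4326,1.5869
1.1565,0.3332,0.0899,1.3419,1.9028,1.1727
-0.7162,0.2878,-0.7775,-1.4111,-0.9699,-1.5933
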