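map,roi,units,n_mean,n_sd,n_cv_pct,mean,sd_inter,cv_pct,sd_intra
T1,cerebral_wm,ms,182915,23808,13,982,22,2,144
T1,caudate,ms,1846,223,12,1335,43,3,111
T1,putamen,ms,2393,568,24,1273,61,5,109
T1,pallidum,ms,1008,291,29,1015,31,3,69
T1,corpus_callosum,ms,1165,147,13,1051,42,4,254
T1,thalamus,ms,5499,1076,20,1195,35,3,151
T1,ventral_dc,ms,3430,707,21,1110,49,4,192
T1,accumbens,ms,296,74,25,1455,56,4,126
T1,amygdala,ms,1077,277,26,1405,137,10,195
T1,hippocampus,ms,2796,984,35,1411,120,9,212
T1,insula,ms,3067,444,14,1524,79,5,203
T1,cortex,ms,91671,11122,12,1423,40,3,291
T2,cerebral_wm,ms,121505,15084,12,58.8,1.4,2,4.8
T2,caudate,ms,1802,195,11,57.9,2.0,3,7.7
T2,putamen,ms,2750,271,10,52.0,2.2,4,4.5
T2,pallidum,ms,963,135,14,42.0,1.5,4,6.3
T2,corpus_callosum,ms,915,120,13,65.7,1.9,3,16.0
T2,thalamus,ms,4205,425,10,56.8,1.3,2,6.1
T2,ventral_dc,ms,2116,229,11,59.2,1.6,3,10.9
T2,accumbens,ms,261,38,14,64.6,1.7,3,6.0
T2,amygdala,ms,691,110,16,68.8,1.6,2,5.5
T2,hippocampus,ms,1855,208,11,71.7,2.3,3,8.5
T2,insula,ms,2719,326,12,69.1,1.3,2,6.9
T2,cortex,ms,69895,6537,9,66.4,1.7,3,8.7
T2star,cerebral_wm,ms,366941,46739,13,49.2,1.7,3,7.3
T2star,caudate,ms,5384,597,11,48.8,3.5,7,10.9
T2star,putamen,ms,8215,811,10,44.2,3.8,9,9.8
T2star,pallidum,ms,2909,403,14,29.5,2.4,8,7.6
T2star,corpus_callosum,ms,2710,365,13,50.5,2.8,5,11.8
T2star,thalamus,ms,12433,1182,10,51.5,4.2,8,10.5
T2star,ventral_dc,ms,6240,606,10,46.3,2.2,5,15.8
T2star,accumbens,ms,764,98,13,59.1,6.4,11,14.6
T2star,amygdala,ms,2027,255,13,67.4,5.0,7,17.4
T2star,hippocampus,ms,5487,529,10,64.4,4.0,6,19.2
T2star,insula,ms,7756,926,12,67.9,2.7,4,16.9
T2star,cortex,ms,219014,17995,8,57.5,2.7,5,15.5
QSM,cerebral_wm,ppm,365817,48168,13,-0.0076,0.0039,-52,0.0371
QSM,caudate,ppm,4329,593,14,0.0849,0.0140,17,0.0349
QSM,putamen,ppm,6982,826,12,0.0765,0.0197,26,0.0521
QSM,pallidum,ppm,2579,416,16,0.2014,0.0246,12,0.0722
QSM,corpus_callosum,ppm,2026,255,13,0.0340,0.0118,35,0.0476
QSM,thalamus,ppm,12370,1314,11,0.0367,0.0095,26,0.0418
QSM,ventral_dc,ppm,6610,730,11,0.0248,0.0128,52,0.0895
QSM,accumbens,ppm,684,109,16,0.0153,0.0283,185,0.0501
QSM,amygdala,ppm,2509,272,11,-0.0150,0.0097,-65,0.0368
QSM,hippocampus,ppm,6332,629,10,-0.0055,0.0117,-215,0.0432
QSM,insula,ppm,6878,903,13,0.0035,0.0069,195,0.0393
QSM,cortex,ppm,219908,19698,9,0.0045,0.0023,51,0.0412
WF,cerebral_wm,%,182878,23798,13,70.5,0.8,1,4.5
WF,caudate,%,1842,222,12,79.6,1.0,1,2.3
WF,putamen,%,2382,567,24,78.0,1.8,2,2.5
WF,pallidum,%,1010,292,29,70.3,1.1,2,2.7
WF,corpus_callosum,%,1173,148,13,71.9,1.2,2,4.8
WF,thalamus,%,5551,1084,20,75.7,0.9,1,3.7
WF,ventral_dc,%,3461,716,21,73.1,1.3,2,5.1
WF,accumbens,%,296,73,25,80.9,1.7,2,2.6
WF,amygdala,%,1077,277,26,80.2,2.9,4,4.5
WF,hippocampus,%,2801,984,35,80.0,2.9,4,4.6
WF,insula,%,3058,435,14,81.2,1.7,2,3.8
WF,cortex,%,91529,11105,12,79.5,1.1,1,10.1
MTVF,cerebral_wm,%,182875,23799,13,29.5,0.8,3,4.5
MTVF,caudate,%,1842,222,12,20.4,1.0,5,2.3
MTVF,putamen,%,2382,567,24,22.0,1.8,8,2.5
MTVF,pallidum,%,1010,292,29,29.7,1.1,4,2.7
MTVF,corpus_callosum,%,1173,148,13,28.1,1.2,4,4.8
MTVF,thalamus,%,5551,1084,20,24.3,0.9,4,3.7
MTVF,ventral_dc,%,3461,716,21,26.9,1.2,5,5.1
MTVF,accumbens,%,296,73,25,19.1,1.7,9,2.6
MTVF,amygdala,%,1077,277,26,19.8,2.9,15,4.5
MTVF,hippocampus,%,2801,984,35,20.0,2.9,14,4.6
MTVF,insula,%,3058,435,14,18.8,1.7,9,3.8
MTVF,cortex,%,91500,11095,12,20.5,1.1,6,10.1
MD,cerebral_wm,1e-4 mm^2/s,363423,48393,13,7.37,0.15,2,0.52
MD,caudate,1e-4 mm^2/s,4261,579,14,8.14,0.43,5,1.99
MD,putamen,1e-4 mm^2/s,6881,816,12,6.94,0.10,1,0.40
MD,pallidum,1e-4 mm^2/s,2587,410,16,6.83,0.15,2,0.51
MD,corpus_callosum,1e-4 mm^2/s,2009,247,12,9.23,0.29,3,2.01
MD,thalamus,1e-4 mm^2/s,12100,1295,11,7.59,0.16,2,1.17
MD,ventral_dc,1e-4 mm^2/s,6467,719,11,8.02,0.48,6,2.09
MD,accumbens,1e-4 mm^2/s,675,109,16,7.90,0.22,3,0.57
MD,amygdala,1e-4 mm^2/s,2469,271,11,8.35,0.21,2,1.51
MD,hippocampus,1e-4 mm^2/s,6240,619,10,8.78,0.32,4,1.45
MD,insula,1e-4 mm^2/s,6806,889,13,8.34,0.18,2,0.91
MD,cortex,1e-4 mm^2/s,223597,19826,9,8.55,0.22,3,1.52
FA,cerebral_wm,unitless,366939,48601,13,0.41,0.01,3,0.14
FA,caudate,unitless,4288,587,14,0.17,0.01,9,0.06
FA,putamen,unitless,6940,816,12,0.20,0.01,8,0.08
FA,pallidum,unitless,2609,415,16,0.33,0.03,8,0.12
FA,corpus_callosum,unitless,2041,255,12,0.61,0.03,5,0.17
FA,thalamus,unitless,12327,1314,11,0.32,0.01,5,0.08
FA,ventral_dc,unitless,6627,735,11,0.46,0.04,8,0.17
FA,accumbens,unitless,678,107,16,0.23,0.04,16,0.07
FA,amygdala,unitless,2496,271,11,0.19,0.01,7,0.06
FA,hippocampus,unitless,6283,617,10,0.18,0.01,6,0.07
FA,insula,unitless,6861,901,13,0.18,0.01,7,0.06
FA,cortex,unitless,224493,20025,9,0.17,0.01,5,0.07
MTR,cerebral_wm,%,366874,49139,13,16.2,0.3,2,0.9
MTR,caudate,%,4325,594,14,13.7,0.5,3,0.9
MTR,putamen,%,6947,822,12,14.1,0.4,3,0.7
MTR,pallidum,%,2608,415,16,14.6,0.4,3,0.7
MTR,corpus_callosum,%,2023,250,12,16.3,0.4,2,1.7
MTR,thalamus,%,12200,1321,11,15.0,0.4,3,0.7
MTR,ventral_dc,%,6556,750,11,14.9,0.5,3,1.2
MTR,accumbens,%,682,108,16,13.0,0.3,3,0.6
MTR,amygdala,%,2495,277,11,14.7,0.4,3,0.9
MTR,hippocampus,%,6337,640,10,14.6,0.4,2,1.0
MTR,insula,%,6876,905,13,14.4,0.3,2,1.1
MTR,cortex,%,224340,20659,9,14.4,0.3,2,1.4
ihMTR,cerebral_wm,%,367002,48965,13,8.2,0.3,3,1.5
ihMTR,caudate,%,4342,599,14,3.2,0.2,8,0.9
ihMTR,putamen,%,6957,822,12,4.0,0.3,6,0.9
ihMTR,pallidum,%,2601,417,16,6.5,0.5,7,1.2
ihMTR,corpus_callosum,%,2034,254,12,7.9,0.4,5,1.6
ihMTR,thalamus,%,12408,1338,11,5.8,0.5,8,1.4
ihMTR,ventral_dc,%,6622,754,11,7.4,0.5,7,1.8
ihMTR,accumbens,%,684,110,16,3.0,0.3,11,0.7
ihMTR,amygdala,%,2510,276,11,4.1,0.3,7,1.0
ihMTR,hippocampus,%,6366,645,10,4.2,0.2,5,1.0
ihMTR,insula,%,6907,925,13,3.4,0.2,5,0.9
ihMTR,cortex,%,224059,20770,9,3.8,0.3,9,1.2
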