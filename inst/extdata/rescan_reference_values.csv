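map,units,mean_diff,sd_diff,loa_upper,loa_lower,slope,intercept,r,p_value
T1,ms,-9.0,58.7,106.1,-124.1,-0.01,7.09,-0.04,0.50
T2,ms,0.16,1.15,2.40,-2.08,0.00,0.22,-0.01,0.91
T2star,ms,-0.29,3.71,6.97,-7.56,0.01,-0.66,0.02,0.73
QSM,ppm,0.001,0.010,0.021,-0.020,-0.004,0.001,-0.03,0.67
WF,%,-0.31,1.49,2.61,-3.23,0.01,-0.01,0.04,0.51
MTVF,%,0.31,1.49,3.23,-2.61,0.01,0.00,0.04,0.51
MD,1e-4 mm^2/s,-0.01,0.15,0.28,-0.31,-0.01,0.07,-0.05,0.37
FA,unitless,0.00,0.01,0.02,-0.02,0.01,0.00,0.10,0.08
MTR,%,-0.10,0.57,1.02,-1.23,-0.09,0.01,-0.16,0.01
ihMTR,%,0.01,0.32,0.65,-0.62,0.01,0.00,0.04,0.47
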