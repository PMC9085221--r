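gene,locus_id,articles,major_minor,maf,accumulated_samples,tsa_result,remaining_samples,or,ci_low,ci_high,p_value,i2
VDR_FokI,rs2228570,3,G/A,0.42,1300,risk,0,1.44,1.22,1.70,0.0001,0
TGFB1_T869C,rs1800470,7,G/A,0.45,3472,risk,0,1.35,1.10,1.65,0.0047,74
IGF1,rs2288377,6,A/T,0.29,4029,risk,0,1.44,1.28,1.62,0.0001,0
IGF1,rs35767,7,G/A,0.37,4575,risk,0,1.20,1.06,1.36,0.0032,47
ESR2_RsaI,rs1256049,1,C/T,0.40,1190,protective,0,0.69,0.59,0.81,0.0001,0
COL1A1_1245GT,rs1800012,1,C/A,0.001,349,not_associated,0,0.83,0.56,1.23,0.3536,0
IGF1,rs5742612,6,A/G,0.29,4031,not_associated,0,1.10,0.97,1.26,0.1394,0
IL6_G174C,rs1800795,1,G/C,0.001,318,not_associated,0,0.61,0.05,7.28,0.6921,0
ESR1_XbaI,rs9340799,7,A/G,0.19,3123,not_associated,0,0.86,0.39,1.89,0.7093,97
ESR1_PvuII,rs2234693,7,T/C,0.40,3010,still_need,2075,0.82,0.55,1.22,0.3210,90
VDR_ApaI,rs7975232,7,C/A,0.29,1804,still_need,1284,1.21,0.81,1.80,0.3442,81
VDR_BsmI,rs1544410,19,C/T,0.06,2473,still_need,7345,1.01,0.64,1.60,0.9525,85
COL1A1_1997GT,rs1107946,2,C/A,0.30,580,still_need,2290,1.21,0.87,1.67,0.2564,25
ESR1_G2014A,rs2228480,3,G/A,0.20,798,still_need,2764,1.00,0.23,4.46,0.9955,97
ESR2_AluI,rs4986938,1,C/T,0.13,1303,still_need,4805,1.31,1.05,1.64,0.0164,0
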