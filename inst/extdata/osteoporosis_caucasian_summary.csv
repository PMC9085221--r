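gene,locus_id,articles,major_minor,maf,accumulated_samples,tsa_result,remaining_samples,or,ci_low,ci_high,p_value,i2
VDR_ApaI,rs7975232,7,C/A,0.45,1728,not_associated,0,0.90,0.72,1.36,0.9579,72
VDR_BsmI,rs1544410,16,C/T,0.40,3620,not_associated,0,0.92,0.76,1.11,0.3841,64
IL6_G174C,rs1800795,9,G/C,0.42,7536,not_associated,0,0.94,0.87,1.01,0.0696,0
COL1A1_1245GT,rs1800012,8,C/A,0.19,1633,not_associated,0,1.27,0.71,2.27,0.4195,88
ESR1_PvuII,rs2234693,7,T/C,0.42,1726,not_associated,0,1.06,0.75,1.50,0.7298,82
ESR1_XbaI,rs9340799,7,A/G,0.31,1839,not_associated,0,0.87,0.58,1.31,0.5099,88
ESR2_RsaI,rs1256049,1,C/T,0.04,380,not_associated,0,1.30,0.81,2.10,0.2740,0
OPG_T245G,rs3134069,2,A/C,0.04,596,not_associated,0,0.79,0.06,10.28,0.8551,68
VDR_FokI,rs2228570,2,G/A,0.38,320,still_need,2305,0.96,0.69,1.34,0.8124,0
VDR_TaqI,rs731236,5,A/G,0.40,1056,still_need,1547,1.34,0.94,1.92,0.1100,68
TGFB1_T869C,rs1800470,3,G/A,0.38,972,still_need,1656,1.03,0.58,1.83,0.9171,70
LRP5,rs3736228,2,C/T,0.13,481,still_need,4459,1.50,1.08,2.07,0.0149,0
ESR1_G2014A,rs2228480,1,G/A,0.17,570,still_need,3448,0.63,0.44,0.90,0.0117,0
ESR2_AluI,rs4986938,3,C/T,0.38,1097,still_need,1531,1.23,0.58,2.57,0.5899,94
OPG_T950C,rs2073617,1,G/A,0.49,555,still_need,1395,0.93,0.73,1.17,0.5118,0
OPG_A163G,rs3102735,2,T/C,0.13,624,still_need,4316,1.49,1.11,2.00,0.0079,0
OPG_G1181C,rs2073618,1,G/C,0.47,555,still_need,2625,0.87,0.70,1.10,0.2523,0
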