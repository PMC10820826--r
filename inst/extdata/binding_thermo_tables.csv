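table,row_id,syringe,cell,kd_um,kd_unc,n,dh,dh_unc,mtds,mtds_unc,dg,dg_unc,fold_kd,binding_detected
1,Mint1_1,Mint1 261-282,Munc18-1,16.3,4.2,0.8,-8.8,0.6,2.8,1.2,-6.5,0.1,NA,TRUE
1,Mint1_1a,Mint1 273-282,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_1b,Mint1 261-272,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_1c,Mint1 266-282,Munc18-1,23.1,1.9,1,-1.2,0.2,-5.4,0.2,-6.39,0.01,NA,TRUE
1,Mint1_4,Mint1 263-282,Munc18-1,12.9,NA,1.3,-2.30,NA,-4.38,NA,-6.70,NA,NA,TRUE
1,Mint1_5,Mint1 265-282,Munc18-1,5.6,NA,1.3,-3.48,NA,-3.69,NA,-7.17,NA,NA,TRUE
1,Mint1_6,Mint1 267-282,Munc18-1,4.0,NA,1.2,-1.29,NA,-6.08,NA,-7.37,NA,NA,TRUE
1,Mint1_7,Mint1 261-280,Munc18-1,19.1,NA,1,-1.78,NA,-4.67,NA,-6.44,NA,NA,TRUE
1,Mint1_8,Mint1 261-278,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_9,Mint1 261-276,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_10,Mint1 261-282 E267A/E268A,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_11,Mint1 261-282 D269A/I270A,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_12,Mint1 261-282 D271A/Q272A,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_13,Mint1 261-282 I273A/V274A,Munc18-1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
1,Mint1_14,Mint1 261-282 A275A/E276A,Munc18-1,216,NA,1.0,-57.6,NA,52.6,NA,-5.00,NA,NA,TRUE
1,Mint1_2,Mint1 257-286,Munc18-1,26.0,NA,1.3,-4.21,NA,-3.41,NA,-7.62,NA,NA,TRUE
1,Mint1_3,Mint1 257-286 phosphomimic,Munc18-1,14.0,NA,1.1,-6.5,NA,-0.103,NA,-6.60,NA,NA,TRUE
1,Mint2_2,Mint2 219-242 phosphomimic,Munc18-1,200,NA,1,-17.2,NA,12.2,NA,-5.05,NA,NA,TRUE
2,Sx1a,Sx1a,Munc18-1,0.07,0.2,1,-22.5,2.4,11.4,2.3,-11.1,0,1,TRUE
2,Sx1a_plus_Mint1,Sx1a + Mint1,Munc18-1 + Mint1,0.27,0.5,1,-29.7,1.9,20.7,2.4,-9.0,0.3,35,TRUE
2,Mint1,Mint1,Munc18-1,8.7,0.2,1,-7.9,0.01,0.9,0.02,-6.9,0.01,1,TRUE
2,Mint1_plus_Sx1a,Mint1,Munc18-1 + Sx1a,20.6,0.7,1,-8.9,1.9,2.5,1.7,-6.4,0.1,2,TRUE
2,Sx1a_dHinge,Sx1a,Munc18-1 d317-333,0.11,NA,1,-18.6,NA,9.1,NA,-9.5,NA,1,TRUE
2,Sx1a_plus_Mint1_dHinge,Sx1a + Mint1,Munc18-1 d317-333 + Mint1,0.09,NA,1,-18.8,NA,9.2,NA,-9.6,NA,1,TRUE
3,TJAP1,TJAP1 9-22,Mint1 PTB,20.9,2.4,1,-8.9,0.9,2.5,0.9,-6.4,0.1,NA,TRUE
3,TJAP1_plus_APP,TJAP1 9-22,Mint1 PTB + APP 750-769,29.4,9.5,1,-7.1,1.6,1.4,1.8,-6.2,0.2,NA,TRUE
3,APP,APP 750-769,Mint1 PTB,0.31,0.01,1,-15.6,0.7,6.7,0.6,-8.9,0.01,NA,TRUE
3,APP_plus_TJAP1,APP 750-769,Mint1 PTB + TJAP1 9-22,0.58,0.01,1,-11.8,0.1,1.7,1.1,-8.5,0.01,NA,TRUE
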