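id,tissue,modality,acquisition_time,n_channels,n_sequences,x_um,y_um,z_um,printed_normalized,printed_decimals,self_consistent,target_id
kidney_lightsheet_half,kidney,light sheet,30:34:29.000,1,1,9251,9199,4590,0.282,3,TRUE,t1
kidney_widefield_half,kidney,widefield,00:02:20.970,1,1,8410,6060,1370,0.002,3,TRUE,t2
kidney_lightsheet_highmag,kidney,light sheet,00:10:02.000,4,4,1109.3,1109.3,1167,0.105,3,TRUE,t3
kidney_confocal,kidney,confocal,01:49:55.517,2,2,455.88,455.88,357.92,44.333,3,TRUE,
ln_lightsheet_whole,lymph node,light sheet,00:09:57.000,6,6,5546.0,5546.0,1250,0.069,3,FALSE,
ln_widefield_whole_10x,lymph node,widefield,00:08:48.142,4,4,2510.86,2506.32,616.41,0.034,3,TRUE,t5
ln_confocal_deep,lymph node,confocal,03:28:43.829,3,2,581.25,581.25,499.42,37.11,2,TRUE,t4
ln_widefield_20x,lymph node,widefield,00:03:44.302,4,4,662.51,662.51,568.12,0.225,3,TRUE,t6
ln_widefield_63x,lymph node,widefield,00:05:05.494,4,4,210.32,210.32,144.02,11.99,2,TRUE,t7
ln_confocal_20x,lymph node,confocal,02:32:07.545,5,5,581.25,581.25,263.24,20.53,2,TRUE,t8
wat_widefield_20x,white adipose tissue,widefield,01:16:27.652,4,4,1848.02,1856.05,1009.20,0.33,2,TRUE,t9
wat_confocal_20x,white adipose tissue,confocal,01:25:35.556,4,3,581.25,581.25,139.42,36.34,2,TRUE,t10
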