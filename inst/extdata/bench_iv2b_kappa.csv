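subject,Twin-SVM,FBCSP,FBCSP_std,CNN-SAE,CNN-SAE_std,IS-CBAM-CNN,IS-CBAM-CNN_std
1,0.494,0.546,0.017,0.517,0.095,0.606,0.030
2,0.416,0.208,0.028,0.324,0.065,0.500,0.036
3,0.322,0.244,0.023,0.494,0.084,0.354,0.052
4,0.897,0.888,0.003,0.905,0.017,0.908,0.012
5,0.722,0.692,0.005,0.655,0.060,0.766,0.030
6,0.405,0.534,0.012,0.579,0.099,0.600,0.034
7,0.466,0.409,0.013,0.488,0.065,0.474,0.044
8,0.477,0.413,0.013,0.494,0.106,0.548,0.040
9,0.503,0.583,0.010,0.463,0.152,0.572,0.042
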