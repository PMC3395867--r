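species,l_um,r_um,lp_um,rp_mean_um,rp_sd_um,n_pores,phi
synthetic_sp_01,594.9,21.8,1.929,3.592,0.943,,0.152
synthetic_sp_02,1141.4,22.59,1.716,2.818,0.707,,0.244
synthetic_sp_03,101.6,7.92,0.644,0.794,0.203,,0.293
synthetic_sp_04,1119.3,19.03,1.891,2.01,0.471,,0.15
synthetic_sp_05,765.9,14.05,1.208,1.019,0.249,,0.319
synthetic_sp_06,133.6,11.53,2.04,2.024,,,0.184
synthetic_sp_07,411.1,16.36,1.469,1.722,,,0.239
synthetic_sp_08,124.9,6.21,1.16,1.074,,,0.347
synthetic_sp_09,729.4,14.39,1.285,2.33,,,0.411
synthetic_sp_10,346.4,15.55,1.229,1.992,,,0.312
synthetic_sp_11,467.1,10.45,1.944,1.829,,,0.203
synthetic_sp_12,596.4,15.91,1.907,1.998,,,0.169
synthetic_sp_13,962.5,22.5,1.279,2.158,,,0.168
synthetic_sp_14,151.2,7.54,0.318,0.733,,,0.223
synthetic_sp_15,359.1,10.52,0.55,1.073,,,0.357
synthetic_sp_16,228.6,22.7,1.911,3.334,,,0.15
synthetic_sp_17,1073.6,24.14,1.374,1.753,,,0.197
synthetic_sp_18,61.2,6.04,0.479,0.858,,,0.504
synthetic_sp_19,155.8,10.74,1.39,1.425,,,0.499
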