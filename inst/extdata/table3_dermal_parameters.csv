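volunteer,parameter,mean,sd
2,k_DDin,0.0005,1E-6
2,k_DinB,0.49,0.01
2,k_DinM_NO_CFMP,0.0001,6E-6
2,k_DinMD_CFMP,0.03,0.01
2,k_MDM_CFMP,0.0530,0.0002
2,k_DinM_NO_3PBA,0.0002,0.0007
2,k_DinMD_3PBA,0.09,7E-6
2,k_MDM_3PBA,0.0001,5E-7
3,k_DDin,0.0005,9E-5
3,k_DinB,0.12,0.01
3,k_DinM_NO_CFMP,0.0003,0.0008
3,k_DinMD_CFMP,0.10,0.03
3,k_MDM_CFMP,0.0001,6E-7
3,k_DinM_NO_3PBA,0.0001,7E-6
3,k_DinMD_3PBA,0.03,0.03
3,k_MDM_3PBA,0.10,0.10
5,k_DDin,0.0009,0.0002
5,k_DinB,0.08,0.02
5,k_DinM_NO_CFMP,0.0001,3E-5
5,k_DinMD_CFMP,0.004,0.04
5,k_MDM_CFMP,0.08,1.1
5,k_DinM_NO_3PBA,0.0001,0.0006
5,k_DinMD_3PBA,0.13,0.03
5,k_MDM_3PBA,0.0002,8E-5
6,k_DDin,0.0004,8E-5
6,k_DinB,0.03,0.01
6,k_DinM_NO_CFMP,0.0001,1E-6
6,k_DinMD_CFMP,0.09,0.01
6,k_MDM_CFMP,0.002,0.005
6,k_DinM_NO_3PBA,0.0002,0.001
6,k_DinMD_3PBA,0.03,0.004
6,k_MDM_3PBA,0.0001,0.05
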