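volunteer,parameter,mean,sd
1,f_abs_oral,0.88,0.18
1,k_abs_oral,2.3,0.54
1,k_BS,0.29,0.09
1,k_SB,0.08,0.00
1,k_BM_CFMP,0.50,0.36
1,k_BM_NO_CFMP,1.5,0.15
1,k_MU_CFMP,0.29,0.02
1,k_MF_CFMP,0.03,0.04
1,k_BM_3PBA,1.3,1.2
1,k_BM_NO_3PBA,0.92,0.42
1,k_MU_3PBA,0.12,0.004
1,k_MF_3PBA,0.02,0.01
2,f_abs_oral,0.96,0.06
2,k_abs_oral,2.3,0.05
2,k_BS,0.06,6E-4
2,k_SB,0.002,1E-5
2,k_BM_CFMP,0.03,0.002
2,k_BM_NO_CFMP,0.03,0.002
2,k_MU_CFMP,0.40,0.002
2,k_MF_CFMP,0.03,0.01
2,k_BM_3PBA,0.09,0.01
2,k_BM_NO_3PBA,0.13,0.01
2,k_MU_3PBA,0.11,0.002
2,k_MF_3PBA,0.01,0.003
3,f_abs_oral,0.79,0.08
3,k_abs_oral,0.89,0.06
3,k_BS,0.20,0.06
3,k_SB,0.07,0.004
3,k_BM_CFMP,0.13,0.02
3,k_BM_NO_CFMP,0.46,0.16
3,k_MU_CFMP,0.25,0.01
3,k_MF_CFMP,0.13,0.38
3,k_BM_3PBA,0.80,0.15
3,k_BM_NO_3PBA,0.95,0.13
3,k_MU_3PBA,0.08,0.01
3,k_MF_3PBA,0.04,0.01
4,f_abs_oral,0.92,0.16
4,k_abs_oral,1.3,0.56
4,k_BS,0.05,0.07
4,k_SB,0.02,0.002
4,k_BM_CFMP,0.08,0.10
4,k_BM_NO_CFMP,0.33,0.41
4,k_MU_CFMP,0.26,0.01
4,k_MF_CFMP,0.007,0.01
4,k_BM_3PBA,0.45,0.59
4,k_BM_NO_3PBA,0.31,0.38
4,k_MU_3PBA,0.09,0.003
4,k_MF_3PBA,0.04,0.01
5,f_abs_oral,0.88,0.16
5,k_abs_oral,1.4,0.46
5,k_BS,0.08,0.04
5,k_SB,0.04,0.003
5,k_BM_CFMP,0.32,0.22
5,k_BM_NO_CFMP,0.48,0.18
5,k_MU_CFMP,0.60,0.03
5,k_MF_CFMP,0.002,6E-5
5,k_BM_3PBA,0.40,0.23
5,k_BM_NO_3PBA,0.43,0.17
5,k_MU_3PBA,0.13,0.003
5,k_MF_3PBA,0.06,0.07
6,f_abs_oral,0.89,0.10
6,k_abs_oral,0.92,0.06
6,k_BS,0.15,0.05
6,k_SB,0.08,0.02
6,k_BM_CFMP,0.16,0.02
6,k_BM_NO_CFMP,0.46,0.16
6,k_MU_CFMP,0.32,0.01
6,k_MF_CFMP,0.10,0.30
6,k_BM_3PBA,0.46,0.09
6,k_BM_NO_3PBA,0.72,0.11
6,k_MU_3PBA,0.09,0.003
6,k_MF_3PBA,0.02,0.01
7,f_abs_oral,0.94,0.12
7,k_abs_oral,0.90,0.02
7,k_BS,0.07,0.02
7,k_SB,0.04,0.01
7,k_BM_CFMP,0.13,0.03
7,k_BM_NO_CFMP,0.61,0.05
7,k_MU_CFMP,0.22,0.002
7,k_MF_CFMP,0.002,4E-5
7,k_BM_3PBA,0.36,0.06
7,k_BM_NO_3PBA,0.63,0.23
7,k_MU_3PBA,0.06,0.01
7,k_MF_3PBA,0.04,0.02
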