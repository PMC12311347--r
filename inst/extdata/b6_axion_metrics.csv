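electrode,n_bursts,mean_duration_s,mean_spikes_per_burst,mean_burst_isi_s
B6_11,141,0.154627,26.049645,0.007177
B6_12,70,0.121345,11.2,0.012619
B6_13,1,0.09224,17,0.005765
B6_14,189,0.193154,41.910053,0.004884
B6_21,1,0.08432,22,0.004015
B6_22,46,0.116901,7.173913,0.018223
B6_23,181,0.147533,26.541436,0.00637
B6_24,17,0.165045,7.529412,0.028814
B6_31,1,0.08336,22,0.00397
B6_32,1,0.112,24,0.00487
B6_33,201,0.145659,30.427861,0.005334
B6_34,185,0.144087,26.313514,0.006126
B6_41,1,0.10288,19,0.005716
B6_42,4,0.0976,9.75,0.018133
B6_43,87,0.148277,11.298851,0.014467
B6_44,211,0.149249,29.753555,0.005208
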