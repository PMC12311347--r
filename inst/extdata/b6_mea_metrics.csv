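electrode,n_bursts,mean_duration_s,mean_spikes_per_burst,mean_burst_isi_s
B6_11,141,0.154547,26.049645,0.007170579
B6_12,70,0.1212651,11.2,0.012609743
B6_13,1,0.09216,17,0.00576
B6_14,189,0.1930743,41.910053,0.004879648
B6_21,1,0.08424,22,0.004011429
B6_22,46,0.1168209,7.173913,0.018208933
B6_23,181,0.1468888,26.524862,0.006349683
B6_24,17,0.1649647,7.529412,0.028800437
B6_31,1,0.08328,22,0.003965714
B6_32,1,0.11192,24,0.004866087
B6_33,201,0.1455781,30.427861,0.005327455
B6_34,185,0.1440069,26.313514,0.006119163
B6_41,1,0.1028,19,0.005711111
B6_42,4,0.09752,9.75,0.018117636
B6_43,87,0.1481968,11.298851,0.014456641
B6_44,211,0.1491685,29.753555,0.005202875
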