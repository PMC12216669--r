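year,group,mean,printed_cv_col,printed_std_col,median
2020,mountain_island,0.355,0.118,0.331,0.318
2020,other,0.504,0.104,0.206,0.504
2021,mountain_island,0.363,0.097,0.268,0.370
2021,other,0.554,0.107,0.192,0.545
2022,mountain_island,0.382,0.103,0.270,0.380
2022,other,0.599,0.114,0.190,0.590
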