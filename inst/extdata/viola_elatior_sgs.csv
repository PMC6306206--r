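population,region,habitat,n_ag,n_sb,F1_ag,F1_sb,b_log_ag,b_log_sb,sp_ag,sp_sb
RM1,R,meadow,21,20,0.000,0.004,-0.004,-0.002,0.004,0.002
RM2,R,meadow,19,7,0.102,0.948,-0.079,-0.085,0.088,1.646
RM3,R,meadow,22,12,0.678,0.357,-0.707,-0.144,2.198,0.223
RM4,R,meadow,22,18,0.391,0.425,-0.428,-0.062,0.703,0.108
RW1,R,woodland,23,9,0.329,0.058,-0.291,-0.001,0.433,0.001
RW2,R,woodland,20,14,0.016,-0.050,-0.021,0.018,0.021,-0.017
RW3,R,woodland,22,10,0.147,0.358,-0.159,-0.085,0.186,0.133
TM1,T,meadow,21,18,-0.021,-0.019,0.007,0.011,-0.007,-0.011
TM2,T,meadow,21,10,0.041,0.334,-0.134,-0.011,0.140,0.017
TM3,T,meadow,21,20,0.515,0.548,-0.487,-0.114,1.003,0.253
TW1,T,woodland,23,21,-0.008,-0.059,-0.010,-0.017,0.010,0.016
TW2,T,woodland,23,20,-0.001,-0.109,-0.042,0.012,0.042,-0.011
TW3,T,woodland,23,19,0.005,0.055,-0.065,-0.013,0.066,0.013
TW4,T,woodland,22,16,0.014,0.265,-0.008,-0.054,0.008,0.073
TW5,T,woodland,21,22,0.160,0.030,-0.067,-0.008,0.079,0.009
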