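population,region,habitat,br_ag,br_sb,plp_ag,plp_sb,pbr_ag,pbr_sb,pu_ag,pu_sb
RM1,R,meadow,1.16,1.12,19,16,0.07,0.03,0.68,0.41
RM2,R,meadow,1.31,1.25,35,31,0.09,0.02,0.86,0.71
RM3,R,meadow,1.34,1.32,34,32,0.03,0.01,0.49,0.45
RM4,R,meadow,1.15,1.15,18,17,0.06,0.06,0.84,0.46
RW1,R,woodland,1.17,1.16,20,20,0.07,0.06,0.92,0.72
RW2,R,woodland,1.06,1.12,9,16,0.03,0.08,0.59,0.79
RW3,R,woodland,1.08,1.06,11,8,0.07,0.04,0.56,0.51
TM1,T,meadow,1.10,1.01,13,2,0.10,0.01,0.42,0.12
TM2,T,meadow,1.06,1.06,7,8,0.02,0.02,0.78,0.56
TM3,T,meadow,1.29,1.28,31,29,0.03,0.02,0.94,0.75
TW1,T,woodland,1.09,1.08,13,11,0.04,0.03,0.93,0.79
TW2,T,woodland,1.05,1.02,8,3,0.04,0.01,0.46,0.27
TW3,T,woodland,1.31,1.40,35,50,0.05,0.15,0.72,0.69
TW4,T,woodland,1.34,1.17,43,20,0.22,0.05,1.00,0.87
TW5,T,woodland,1.04,1.05,5,6,0.01,0.02,0.45,0.61
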