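theta_deg,A1,A2,A3,A4,A5,A6,A7,A8
5,0.361,0.013,0.016,0.023,0.149,0.020,0.011,0.004
10,0.320,0.008,0.020,0.023,0.148,0.019,0.012,0.005
15,0.292,0.007,0.025,0.022,0.143,0.018,0.012,0.004
20,0.237,0.005,0.032,0.023,0.120,0.022,0.012,0.004
30,0.184,0.006,0.039,0.016,0.092,0.017,0.015,0.003
40,0.143,0.006,0.043,0.012,0.066,0.014,0.015,0.004
50,0.106,0.006,0.041,0.007,0.041,0.007,0.012,0.003
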