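population,t_up,one_plus_s_up,se,g150_pct,g250_pct
gln_01,70,1.066,0.0038,62,77
gln_02,75,1.071,0.0034,57,87
gln_03,70,1.071,0.0037,88,94
gln_04,70,1.079,0.0036,80,95
gln_05,75,1.077,0.0041,74,89
gln_06,70,1.082,0.0043,91,75
gln_07,75,1.094,0.0048,18,78
gln_08,75,1.090,0.0052,90,82
gln_09,75,1.066,0.0050,48,93
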