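population,generation,detected,fp_rate
bc01,70,9650,0.27
bc01,90,1064,0.09
bc01,150,136,0.04
bc01,270,79,0.04
bc02,70,7243,0.27
bc02,90,5851,0.09
bc02,150,606,0.04
bc02,270,29,0.04
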