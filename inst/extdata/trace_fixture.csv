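# kind=delta_i_over_i sample_rate=500 t0=0
time_s,value
0,0.01
0.002,-0.02
0.004,0.03
0.006,-0.04
0.008,0.05
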