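state,description,lower,upper
E1,strong decreasing year,0.60,0.75
E2,poor decreasing year,0.75,0.90
E3,poor increasing year,0.90,1.05
E4,strong increasing year,1.05,1.20
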