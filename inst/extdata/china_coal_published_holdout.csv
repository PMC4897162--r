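year,actual,amended_prediction,amended_error,markov_prediction,markov_error
2004,6027,5433,0.099,6112,0.014
2005,5986,5233,0.126,5887,0.017
2006,4746,5040,0.062,4914,0.035
2007,3786,3970,0.049,3870,0.022
2008,2631,3846,0.462,3749,0.425
2009,2631,3725,0.416,2328,0.115
2010,2433,3592,0.476,2424,0.004
2011,1973,3357,0.701,2265,0.147
2012,1384,2142,0.548,1446,0.045
2013,1067,1934,0.813,1305,0.223
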