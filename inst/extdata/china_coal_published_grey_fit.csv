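year,actual,grey_prediction
1990,7185,NA
1991,6269,7716
1992,5854,7451
1993,5152,7196
1994,6574,6949
1995,6222,6710
1996,6496,6479
1997,6141,6257
1998,6304,6042
1999,6478,5835
2000,5798,5635
2001,5670,5441
2002,6995,5254
2003,6702,5074
2004,6027,4899
2005,5986,4731
2006,4746,4569
2007,3786,4412
2008,2631,4261
2009,2631,4114
2010,2433,3987
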