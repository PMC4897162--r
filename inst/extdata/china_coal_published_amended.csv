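year,actual,amended_prediction,ratio_percent
1991,6269,6501,96
1992,5854,6310,93
1993,5152,6125,84
1994,6574,5944,111
1995,6222,5766,108
1996,6496,5565,88
1997,6141,5425,113
1998,6304,6823,93
1999,6478,6568,119
2000,5798,6323,118
2001,5670,6087,111
2002,6995,5860,114
2003,6702,5643,119
2004,6027,5433,111
2005,5986,5233,114
2006,4746,5040,94
2007,3786,3970,95
2008,2631,3846,69
2009,2631,3725,71
2010,2433,3592,68
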