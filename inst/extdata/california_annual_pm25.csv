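year,all_mean,all_sd,fire_mean,fire_sd,pct_fire
2007,4.62,2.27,0.87,1.55,18.9
2008,8.90,8.76,4.40,8.89,49.4
2009,4.77,1.50,0.61,0.91,12.7
2010,4.60,1.51,0.31,0.47,6.8
2011,3.90,1.43,0.50,0.70,12.8
2012,3.84,1.51,0.71,1.16,18.4
2013,3.74,1.94,1.16,1.89,30.9
average,4.91,4.04,1.22,3.78,24.9
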