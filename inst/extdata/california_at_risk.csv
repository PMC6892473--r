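class,asthma_ed,births,heart_attack,poverty,under18,over65,total_population
Total,2908,591359,1574,13.67,10.60,4.67,36.78
1,677,241761,350,5.73,4.44,1.92,17.45
2,489,84170,235,1.85,1.52,0.65,5.87
3,626,141995,336,3.37,2.52,1.08,9.77
4,1079,114496,634,2.49,2.02,0.91,7.87
Missing,38,8936,20,0.22,0.11,0.11,0.80
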