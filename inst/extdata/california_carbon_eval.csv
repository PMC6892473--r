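stratum,year,n,mean_obs,mean_pred,difference
wildfire-impacted,2007,463,4.1,4.5,0.5
wildfire-impacted,2008,721,5.2,7.1,2.0
wildfire-impacted,2009,422,5.6,3.5,-2.1
wildfire-impacted,2010,220,3.8,3.0,-0.8
wildfire-impacted,2011,428,3.5,3.2,-0.3
wildfire-impacted,2012,418,3.9,3.7,-0.1
wildfire-impacted,2013,589,3.7,5.3,1.6
little-or-no,2007,918,1.6,1.1,-0.5
little-or-no,2008,599,1.5,1.5,-0.1
little-or-no,2009,966,1.4,1.2,-0.2
little-or-no,2010,1158,1.4,1.2,-0.2
little-or-no,2011,947,1.3,1.0,-0.4
little-or-no,2012,1008,1.3,1.0,-0.4
little-or-no,2013,776,1.2,0.7,-0.5
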