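drug,n_reports,dili_reports,dili_prop,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,ebgm05
crizotinib,19857,696,3.51,3.54,3.28,3.82,3.45,1220.66,1.78,0.12,3.45,3.23
ceritinib,8946,451,5.04,5.25,4.77,5.77,5.03,1470.92,2.33,0.66,5.03,4.65
alectinib,12141,528,4.35,4.49,4.12,4.90,4.34,1369.30,2.12,0.45,4.34,4.03
brigatinib,7468,178,2.38,2.40,2.07,2.78,2.37,141.76,1.24,-0.42,2.37,2.09
lorlatinib,8452,125,1.48,1.49,1.25,1.77,1.48,19.61,0.56,-1.10,1.48,1.28
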