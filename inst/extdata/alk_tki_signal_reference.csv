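drug,level,event,n,ror,ror_low,ror_high,prr,chi2,ic,ic025,ebgm,ebgm05
crizotinib,SOC,"neoplasms benign, malignant and unspecified (incl cysts and polyps)",1738,3.46,3.29,3.63,3.24,2766.34,1.70,0.03,3.24,3.11
crizotinib,SOC,eye disorders,883,2.38,2.23,2.55,2.32,676.52,1.21,-0.45,2.32,2.19
ceritinib,SOC,gastrointestinal disorders,1557,2.33,2.20,2.46,2.09,940.32,1.06,-0.60,2.09,2.00
ceritinib,SOC,"neoplasms benign, malignant and unspecified (incl cysts and polyps)",1543,7.22,6.82,7.64,6.14,6534.70,2.62,0.95,6.14,5.86
ceritinib,SOC,metabolism and nutrition disorders,369,2.10,1.89,2.33,2.05,200.02,1.04,-0.63,2.05,1.88
ceritinib,SOC,hepatobiliary disorders,252,3.68,3.25,4.18,3.61,472.62,1.85,0.18,3.60,3.24
alectinib,SOC,hepatobiliary disorders,319,3.30,2.96,3.69,3.24,498.68,1.70,0.03,3.24,2.95
brigatinib,SOC,"neoplasms benign, malignant and unspecified (incl cysts and polyps)",1106,5.40,5.07,5.76,4.75,3374.71,2.25,0.58,4.74,4.50
lorlatinib,SOC,metabolism and nutrition disorders,410,2.58,2.34,2.85,2.51,378.10,1.32,-0.34,2.50,2.31
crizotinib,PT,photopsia,115,61.48,51.08,73.99,61.13,6656.83,5.90,4.24,59.84,51.25
lorlatinib,PT,hypercholesterolemia,92,100.00,81.20,123.15,98.92,8680.41,6.59,4.92,96.31,80.91
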