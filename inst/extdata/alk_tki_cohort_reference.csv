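drug,block,category,count,pct
crizotinib,total,total,19857,NA
ceritinib,total,total,8946,NA
alectinib,total,total,12141,NA
brigatinib,total,total,7468,NA
lorlatinib,total,total,8452,NA
crizotinib,sex,Female,10748,54.13
crizotinib,sex,Male,7770,39.13
crizotinib,sex,Unknown,1339,6.74
ceritinib,sex,Female,4639,51.86
ceritinib,sex,Male,3646,40.76
ceritinib,sex,Unknown,661,7.39
alectinib,sex,Female,6977,57.47
alectinib,sex,Male,4235,34.88
alectinib,sex,Unknown,929,7.65
brigatinib,sex,Female,4221,56.52
brigatinib,sex,Male,2750,36.82
brigatinib,sex,Unknown,497,6.66
lorlatinib,sex,Female,4370,51.70
lorlatinib,sex,Male,3306,39.12
lorlatinib,sex,Unknown,776,9.18
crizotinib,country,United States,11814,59.50
crizotinib,country,Japan,1670,8.41
crizotinib,country,China,527,2.65
crizotinib,country,Other,5846,29.44
ceritinib,country,United States,1832,20.48
ceritinib,country,Japan,1357,15.17
ceritinib,country,China,638,7.13
ceritinib,country,Other,5119,57.22
alectinib,country,United States,6749,55.59
alectinib,country,Japan,974,8.02
alectinib,country,China,572,4.71
alectinib,country,Other,3846,31.68
brigatinib,country,United States,3984,53.35
brigatinib,country,Japan,1294,17.33
brigatinib,country,China,48,0.64
brigatinib,country,Other,2142,28.68
lorlatinib,country,United States,2695,31.89
lorlatinib,country,Japan,1079,12.77
lorlatinib,country,China,269,3.18
lorlatinib,country,Other,4409,52.17
crizotinib,reporter,Physician,7450,37.52
crizotinib,reporter,Consumer,5587,28.14
crizotinib,reporter,Pharmacist,2332,11.74
crizotinib,reporter,Other health professional,4394,22.13
crizotinib,reporter,Unknown,94,0.47
ceritinib,reporter,Physician,3644,40.73
ceritinib,reporter,Consumer,3037,33.95
ceritinib,reporter,Pharmacist,350,3.91
ceritinib,reporter,Other health professional,1491,16.67
ceritinib,reporter,Unknown,424,4.74
alectinib,reporter,Physician,4193,34.54
alectinib,reporter,Consumer,5657,46.59
alectinib,reporter,Pharmacist,951,7.83
alectinib,reporter,Other health professional,1238,10.20
alectinib,reporter,Unknown,102,0.84
brigatinib,reporter,Physician,3041,40.72
brigatinib,reporter,Consumer,2629,35.20
brigatinib,reporter,Pharmacist,521,6.89
brigatinib,reporter,Other health professional,1272,17.03
brigatinib,reporter,Unknown,5,0.07
lorlatinib,reporter,Physician,3253,38.49
lorlatinib,reporter,Consumer,3377,39.96
lorlatinib,reporter,Pharmacist,563,6.66
lorlatinib,reporter,Other health professional,1136,13.44
lorlatinib,reporter,Unknown,123,1.46
crizotinib,outcome,Death,5232,26.35
crizotinib,outcome,Hospitalization,4200,21.15
crizotinib,outcome,Life threatening,348,1.75
crizotinib,outcome,Disability,86,0.43
crizotinib,outcome,Other serious,3896,19.62
crizotinib,outcome,Unknown,6095,30.69
ceritinib,outcome,Death,2556,28.57
ceritinib,outcome,Hospitalization,2152,24.06
ceritinib,outcome,Life threatening,242,2.71
ceritinib,outcome,Disability,87,0.97
ceritinib,outcome,Other serious,3067,34.28
ceritinib,outcome,Unknown,842,9.41
alectinib,outcome,Death,1336,11.00
alectinib,outcome,Hospitalization,2697,22.21
alectinib,outcome,Life threatening,236,1.94
alectinib,outcome,Disability,128,1.05
alectinib,outcome,Other serious,4488,36.97
alectinib,outcome,Unknown,3256,26.82
brigatinib,outcome,Death,1379,18.47
brigatinib,outcome,Hospitalization,2004,26.83
brigatinib,outcome,Life threatening,72,0.96
brigatinib,outcome,Disability,34,0.46
brigatinib,outcome,Other serious,3183,42.62
brigatinib,outcome,Unknown,796,10.66
lorlatinib,outcome,Death,2116,25.04
lorlatinib,outcome,Hospitalization,1784,21.11
lorlatinib,outcome,Life threatening,142,1.68
lorlatinib,outcome,Disability,93,1.10
lorlatinib,outcome,Other serious,3120,36.91
lorlatinib,outcome,Unknown,1197,14.16
crizotinib,onset,0-7,1570,7.91
crizotinib,onset,7-28,1600,8.06
crizotinib,onset,28-60,857,4.32
crizotinib,onset,>=60,2072,10.43
crizotinib,onset,Unknown,13758,69.29
ceritinib,onset,0-7,1294,14.46
ceritinib,onset,7-28,1179,13.18
ceritinib,onset,28-60,642,7.18
ceritinib,onset,>=60,1707,19.08
ceritinib,onset,Unknown,4124,46.10
alectinib,onset,0-7,111,0.91
alectinib,onset,7-28,351,2.89
alectinib,onset,28-60,249,2.05
alectinib,onset,>=60,452,3.72
alectinib,onset,Unknown,9612,79.17
brigatinib,onset,0-7,531,7.11
brigatinib,onset,7-28,330,4.42
brigatinib,onset,28-60,153,2.05
brigatinib,onset,>=60,470,6.29
brigatinib,onset,Unknown,5984,80.13
lorlatinib,onset,0-7,222,2.63
lorlatinib,onset,7-28,408,4.83
lorlatinib,onset,28-60,352,4.16
lorlatinib,onset,>=60,738,8.73
lorlatinib,onset,Unknown,6448,76.29
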