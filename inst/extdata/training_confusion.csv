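procedure,description,TP,TN,FP,FN
1,Docking score threshold,97,1157,323,108
2,Bayesian on scores,89,1232,248,116
3,Logistic regression on Bayesian,100,1078,402,105
4,Modified Bayesian,90,1233,247,115
5,Fingerprints (ECFP),189,795,685,16
6,Docking scores then ECFP,169,978,502,36
7,ECFP then docking scores,191,712,768,14
8,Logistic regr. on docking scores and ECFP,71,1463,17,134
9,Consensus Docking and ECFP else 8,170,1054,426,35
10,Consensus Bayesian and ECFP else 8,117,1302,178,88
11,Logistic regr. on docking scores and ECFP and ratio of Bayesian,69,1463,17,136
12,Logistic regression on Bayesian avgs. and fingerprints,42,1462,18,163
13,Logistic regression on docking scores and Bayesian avgs. and fingerprints,75,1469,11,130
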