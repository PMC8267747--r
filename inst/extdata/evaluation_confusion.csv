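procedure,TP,TN,FP,FN
13,36,3395,34,418
5,217,2713,716,235
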