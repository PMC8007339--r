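drug,week,pct_remaining
amlodipine,0,102.1
amlodipine,1,101.8
amlodipine,2,99.1
amlodipine,3,98.3
amlodipine,4,97.3
valsartan,0,106.2
valsartan,1,105.3
valsartan,2,102.2
valsartan,3,101.9
valsartan,4,101.1
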