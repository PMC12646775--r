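characteristic,level,n
touch,no,117614
touch,yes,27850
touch,unknown,196
frequency,<1/wk,24304
frequency,1-3/wk,15370
frequency,4+/wk,105938
frequency,unknown,48
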