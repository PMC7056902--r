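id,trait,sex,batch
bird1,2100,M,1
bird2,1950,F,1
bird3,2300,M,2
bird4,1800,F,2
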