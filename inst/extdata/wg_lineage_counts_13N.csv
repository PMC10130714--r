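age,total,south,north
135,3,0,0
120,12,5,0
90,54,11,0
60,85,18,1
30,153,35,5
10,337,114,13
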