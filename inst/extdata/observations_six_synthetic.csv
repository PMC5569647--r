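id,time,value
l1,1970,0
l1,1973,1
l2,1980,0
l2,1984,1
l3,1990,1
l3,1993,1
l4,1975,0
l4,1979,1
l5,2000,0
l5,2010,1
l6,1990,0
l6,1996,1
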