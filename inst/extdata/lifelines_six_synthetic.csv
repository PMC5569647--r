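id,birth,death
l1,1900,1975
l2,1910,1985
l3,1905,1995
l4,1920,1980
l5,1930,2012
l6,1915,1997
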