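case,A,P,C,T,D,L
tp_d,,1971,,30,,
pd_t,,1953,,,1973,
td_p,,,,30,1974,
tl_a,,,,20,,86
al_t,34,,,,,96
lc_d,,,1940,,,64
cd_l,,,1893,,1964,
ld_c,,,,,1996,96
ap_c,50,1963.3832991,,,,
ac_p,30,,1941,,,
cp_a,,2000,1950,,,
ta_l,66,,,20,,
lp_none,,2016,,,,100
ct_none,,,1950,10,,
ad_none,80,,,,2000,
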