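locus,r_cumulative,null_rank
SPB2727,0,14
Dfr-09,0,14
Dfr-16,0,14
SPB3731,0,14
Dfr-10,0,14
SPB2313,0,14
SPB0138,0,14
SPB1983,0,14
Dfr-24,0.318,5
Dfr-14,0,14
Dfr-17,0,14
SPB2613,0.327,4
SPB1230,0,14
Dfr-18,0,14
SPB1875,0,14
SPB3013,0,14
SPB1272,0,14
SPB1284,0.248,7
SPB1242,0,14
SPB2480,1.405,1
Dfr-06,0,14
SPB1507,0.843,2
SPB2187,0.148,12
SPB1270,0.161,10
SPB4422,0.239,8
SPB903595,0.268,6
SPB180144,0.228,9
SPB265317,0.149,11
SPB979494,0,14
SPB4155,0.426,3
SPB3702,0,14
SPB1278,0,14
SPB1534,0.145,13
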