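locus,fst,rank
SPB2727,0.025,11
Dfr-09,0.027,9
Dfr-16,0.023,15
SPB3731,0.035,4
Dfr-10,0.022,18
SPB2313,0.014,31
SPB0138,0.006,33
SPB1983,0.018,25
Dfr-24,0.024,12
Dfr-14,0.019,22
Dfr-17,0.028,8
SPB2613,0.018,24
SPB1230,0.012,32
Dfr-18,0.017,27
SPB1875,0.022,19
SPB3013,0.028,7
SPB1272,0.027,10
SPB1284,0.028,6
SPB1242,0.019,23
SPB2480,0.064,1
Dfr-06,0.015,29
SPB1507,0.017,26
SPB2187,0.036,3
SPB1270,0.023,16
SPB4422,0.023,14
SPB903595,0.031,5
SPB180144,0.017,28
SPB265317,0.023,17
SPB979494,0.023,13
SPB4155,0.039,2
SPB3702,0.021,20
SPB1278,0.015,30
SPB1534,0.019,21
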