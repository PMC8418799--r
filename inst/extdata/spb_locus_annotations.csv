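name,seq_repeats,seq_allele_length,median_allele_length,median_repeats_printed,repeat_rank
SPB2727,7,144,141.5,6.88,19
Dfr-09,10,109,104.5,9.59,5
Dfr-16,11,191,183,10.54,3
SPB3731,6,145,142,5.88,31
Dfr-10,13,158,149.5,12.3,2
SPB2313,9,296,292.5,8.89,9
SPB0138,6,115,116,6.05,27
SPB1983,7,143,142,6.95,18
Dfr-24,15,151,150,14.9,1
Dfr-14,9,188,190,9.1,8
Dfr-17,9,122,126,9.3,6
SPB2613,7,283,291.5,7.21,14
SPB1230,7,219,227.5,7.27,13
Dfr-18,7,130,136.5,7.35,12
SPB1875,6,110,118,6.44,22
SPB3013,6,154,156.5,6.1,25
SPB1272,9,263,259.5,8.88,10
SPB1284,8,130,126,7.75,11
SPB1242,6,146,144,5.92,30
SPB2480,6,162,164.5,6.09,26
Dfr-06,10,139,139,10,4
SPB1507,7,146,149,7.14,15
SPB2187,6,196,194,5.94,29
SPB1270,9,243,246,9.11,7
SPB4422,7,244,230,6.6,21
SPB903595,5,275,272,4.95,33
SPB180144,7,174,177,7.12,16
SPB265317,6,386,389,6.05,28
SPB979494,7,215,205.5,6.69,20
SPB4155,7,107,108,7.07,17
SPB3702,6,109,103.5,5.7,32
SPB1278,6,108,110,6.11,24
SPB1534,6,116,120.5,6.23,23
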