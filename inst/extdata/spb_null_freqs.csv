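locus,pop,r_hat,significant
SPB2727,AL,0,FALSE
SPB2727,FL,0,FALSE
SPB2727,GA,0,FALSE
SPB2727,LA,0.116,FALSE
SPB2727,MS-Hol,0.273,FALSE
SPB2727,MS-Tom,0,FALSE
SPB2727,PA,0,FALSE
Dfr-09,AL,0,FALSE
Dfr-09,FL,0.043,FALSE
Dfr-09,GA,0,FALSE
Dfr-09,LA,0.021,FALSE
Dfr-09,MS-Hol,0,FALSE
Dfr-09,MS-Tom,0.071,FALSE
Dfr-09,PA,0,FALSE
Dfr-16,AL,0.001,FALSE
Dfr-16,FL,0,FALSE
Dfr-16,GA,0.096,FALSE
Dfr-16,LA,0,FALSE
Dfr-16,MS-Hol,0.008,FALSE
Dfr-16,MS-Tom,0,FALSE
Dfr-16,PA,0,FALSE
SPB3731,AL,0,FALSE
SPB3731,FL,0,FALSE
SPB3731,GA,0.14,FALSE
SPB3731,LA,0.008,FALSE
SPB3731,MS-Hol,0,FALSE
SPB3731,MS-Tom,0.104,FALSE
SPB3731,PA,0,FALSE
Dfr-10,AL,0.055,FALSE
Dfr-10,FL,0,FALSE
Dfr-10,GA,0,FALSE
Dfr-10,LA,0.029,FALSE
Dfr-10,MS-Hol,0,FALSE
Dfr-10,MS-Tom,0.011,FALSE
Dfr-10,PA,0,FALSE
SPB2313,AL,0.08,FALSE
SPB2313,FL,0.046,FALSE
SPB2313,GA,0.033,FALSE
SPB2313,LA,0,FALSE
SPB2313,MS-Hol,0.156,FALSE
SPB2313,MS-Tom,0.005,FALSE
SPB2313,PA,0.002,FALSE
SPB0138,AL,0,FALSE
SPB0138,FL,0,FALSE
SPB0138,GA,0,FALSE
SPB0138,LA,0,FALSE
SPB0138,MS-Hol,0,FALSE
SPB0138,MS-Tom,0,FALSE
SPB0138,PA,0,FALSE
SPB1983,AL,0.055,FALSE
SPB1983,FL,0,FALSE
SPB1983,GA,0.015,FALSE
SPB1983,LA,0,FALSE
SPB1983,MS-Hol,0,FALSE
SPB1983,MS-Tom,0,FALSE
SPB1983,PA,0,FALSE
Dfr-24,AL,0.179,TRUE
Dfr-24,FL,0.043,FALSE
Dfr-24,GA,0,FALSE
Dfr-24,LA,0.016,FALSE
Dfr-24,MS-Hol,0.139,TRUE
Dfr-24,MS-Tom,0,FALSE
Dfr-24,PA,0.011,FALSE
Dfr-14,AL,0.093,FALSE
Dfr-14,FL,0,FALSE
Dfr-14,GA,0,FALSE
Dfr-14,LA,0,FALSE
Dfr-14,MS-Hol,0,FALSE
Dfr-14,MS-Tom,0.082,FALSE
Dfr-14,PA,0,FALSE
Dfr-17,AL,0.01,FALSE
Dfr-17,FL,0.013,FALSE
Dfr-17,GA,0.082,FALSE
Dfr-17,LA,0,FALSE
Dfr-17,MS-Hol,0,FALSE
Dfr-17,MS-Tom,0.05,FALSE
Dfr-17,PA,0,FALSE
SPB2613,AL,0.033,FALSE
SPB2613,FL,0.327,TRUE
SPB2613,GA,0.021,FALSE
SPB2613,LA,0,FALSE
SPB2613,MS-Hol,0,FALSE
SPB2613,MS-Tom,0.012,FALSE
SPB2613,PA,0,FALSE
SPB1230,AL,0.02,FALSE
SPB1230,FL,0,FALSE
SPB1230,GA,0,FALSE
SPB1230,LA,0,FALSE
SPB1230,MS-Hol,0,FALSE
SPB1230,MS-Tom,0,FALSE
SPB1230,PA,0,FALSE
Dfr-18,AL,0.032,FALSE
Dfr-18,FL,0,FALSE
Dfr-18,GA,0.024,FALSE
Dfr-18,LA,0,FALSE
Dfr-18,MS-Hol,0.021,FALSE
Dfr-18,MS-Tom,0,FALSE
Dfr-18,PA,0,FALSE
SPB1875,AL,0,FALSE
SPB1875,FL,0.009,FALSE
SPB1875,GA,0,FALSE
SPB1875,LA,0,FALSE
SPB1875,MS-Hol,0,FALSE
SPB1875,MS-Tom,0,FALSE
SPB1875,PA,0,FALSE
SPB3013,AL,0.042,FALSE
SPB3013,FL,0,FALSE
SPB3013,GA,0,FALSE
SPB3013,LA,0,FALSE
SPB3013,MS-Hol,0,FALSE
SPB3013,MS-Tom,0,FALSE
SPB3013,PA,0.136,FALSE
SPB1272,AL,0.017,FALSE
SPB1272,FL,0,FALSE
SPB1272,GA,0,FALSE
SPB1272,LA,0,FALSE
SPB1272,MS-Hol,0,FALSE
SPB1272,MS-Tom,0,FALSE
SPB1272,PA,0.043,FALSE
SPB1284,AL,0,FALSE
SPB1284,FL,0.041,FALSE
SPB1284,GA,0,FALSE
SPB1284,LA,0,FALSE
SPB1284,MS-Hol,0.248,TRUE
SPB1284,MS-Tom,0.052,FALSE
SPB1284,PA,0.013,FALSE
SPB1242,AL,0.044,FALSE
SPB1242,FL,0,FALSE
SPB1242,GA,0,FALSE
SPB1242,LA,0.044,FALSE
SPB1242,MS-Hol,0,FALSE
SPB1242,MS-Tom,0.142,FALSE
SPB1242,PA,0,FALSE
SPB2480,AL,0.431,TRUE
SPB2480,FL,0.134,FALSE
SPB2480,GA,0,FALSE
SPB2480,LA,0.208,FALSE
SPB2480,MS-Hol,0.324,TRUE
SPB2480,MS-Tom,0.246,TRUE
SPB2480,PA,0.404,TRUE
Dfr-06,AL,0.048,FALSE
Dfr-06,FL,0.044,FALSE
Dfr-06,GA,0.046,FALSE
Dfr-06,LA,0.054,FALSE
Dfr-06,MS-Hol,0.069,FALSE
Dfr-06,MS-Tom,0.099,FALSE
Dfr-06,PA,0.054,FALSE
SPB1507,AL,0.162,TRUE
SPB1507,FL,0.089,FALSE
SPB1507,GA,0.235,TRUE
SPB1507,LA,0.085,FALSE
SPB1507,MS-Hol,0.197,TRUE
SPB1507,MS-Tom,0.094,FALSE
SPB1507,PA,0.249,TRUE
SPB2187,AL,0.014,FALSE
SPB2187,FL,0,FALSE
SPB2187,GA,0.071,FALSE
SPB2187,LA,0.058,FALSE
SPB2187,MS-Hol,0,FALSE
SPB2187,MS-Tom,0.148,TRUE
SPB2187,PA,0.064,FALSE
SPB1270,AL,0.161,TRUE
SPB1270,FL,0.106,FALSE
SPB1270,GA,0,FALSE
SPB1270,LA,0,FALSE
SPB1270,MS-Hol,0.156,FALSE
SPB1270,MS-Tom,0,FALSE
SPB1270,PA,0,FALSE
SPB4422,AL,0,FALSE
SPB4422,FL,0,FALSE
SPB4422,GA,0,FALSE
SPB4422,LA,0,FALSE
SPB4422,MS-Hol,0,FALSE
SPB4422,MS-Tom,0,FALSE
SPB4422,PA,0.239,TRUE
SPB903595,AL,0,FALSE
SPB903595,FL,0,FALSE
SPB903595,GA,0.106,FALSE
SPB903595,LA,0,FALSE
SPB903595,MS-Hol,0.053,FALSE
SPB903595,MS-Tom,0.268,TRUE
SPB903595,PA,0,FALSE
SPB180144,AL,0.024,FALSE
SPB180144,FL,0.025,FALSE
SPB180144,GA,0,FALSE
SPB180144,LA,0.228,TRUE
SPB180144,MS-Hol,0.083,FALSE
SPB180144,MS-Tom,0.016,FALSE
SPB180144,PA,0.012,FALSE
SPB265317,AL,0.054,FALSE
SPB265317,FL,0.094,FALSE
SPB265317,GA,0.149,TRUE
SPB265317,LA,0.088,FALSE
SPB265317,MS-Hol,0,FALSE
SPB265317,MS-Tom,0.092,FALSE
SPB265317,PA,0.083,FALSE
SPB979494,AL,0,FALSE
SPB979494,FL,0,FALSE
SPB979494,GA,0.078,FALSE
SPB979494,LA,0,FALSE
SPB979494,MS-Hol,0,FALSE
SPB979494,MS-Tom,0,FALSE
SPB979494,PA,0.068,FALSE
SPB4155,AL,0.053,FALSE
SPB4155,FL,0,FALSE
SPB4155,GA,0.426,TRUE
SPB4155,LA,0.037,FALSE
SPB4155,MS-Hol,0.076,FALSE
SPB4155,MS-Tom,0,FALSE
SPB4155,PA,0,FALSE
SPB3702,AL,0.006,FALSE
SPB3702,FL,0.006,FALSE
SPB3702,GA,0,FALSE
SPB3702,LA,0,FALSE
SPB3702,MS-Hol,0.065,FALSE
SPB3702,MS-Tom,0,FALSE
SPB3702,PA,0.223,FALSE
SPB1278,AL,0,FALSE
SPB1278,FL,0,FALSE
SPB1278,GA,0,FALSE
SPB1278,LA,0,FALSE
SPB1278,MS-Hol,0.073,FALSE
SPB1278,MS-Tom,0.044,FALSE
SPB1278,PA,0,FALSE
SPB1534,AL,0.145,TRUE
SPB1534,FL,0,FALSE
SPB1534,GA,0,FALSE
SPB1534,LA,0.021,FALSE
SPB1534,MS-Hol,0.026,FALSE
SPB1534,MS-Tom,0.002,FALSE
SPB1534,PA,0.069,FALSE
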