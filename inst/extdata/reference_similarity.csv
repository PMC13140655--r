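sex,restExercise.CTR,restExercise.HY1,restExercise.HY2,CTR-HY1.rest,CTR-HY1.exercise,CTR-HY2.rest,CTR-HY2.exercise,HY1-HY2.rest,HY1-HY2.exercise
F,0.388,0.270,0.330,0.306,0.135,0.376,0.327,0.295,0.144
F,0.499,0.510,0.501,0.589,0.419,0.586,0.508,0.512,0.386
F,0.535,0.330,0.377,0.431,0.513,0.397,0.466,0.478,0.469
F,0.462,0.125,0.342,0.187,0.442,0.357,0.474,0.134,0.643
F,0.326,0.042,0.445,0.032,0.482,0.137,0.459,0.079,0.379
F,0.200,0.098,0.285,0.256,0.395,0.288,0.216,0.328,0.146
M,0.268,0.116,0.262,0.111,0.035,0.231,0.270,0.076,0.024
M,0.367,0.165,0.537,0.200,0.326,0.392,0.317,0.223,0.216
M,0.533,0.296,0.317,0.297,0.422,0.482,0.382,0.325,0.358
M,0.097,0.280,0.199,0.250,0.408,0.286,0.402,0.204,0.535
M,0.369,0.317,0.307,0.362,0.461,0.418,0.478,0.391,0.315
M,0.250,0.274,0.407,0.330,0.227,0.337,0.298,0.427,0.386
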