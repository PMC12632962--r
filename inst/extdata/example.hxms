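METADATA	PROTEIN_SEQUENCE	GSHMKTVEVNGADASDDN
METADATA	PROTEIN_NAME	synthetic model protein
METADATA	PROTEIN_STATE	APO
METADATA	TEMPERATURE (K)	293.15
METADATA	pH(READ)	6
METADATA	D2O_SATURATION	0.91
TP          0       A      1      10     0    0000    0.000000e+00    0.00     0.976,0.000,0.002,0.003,0.002,0.000,0.007,0.000,0.010
TP          1       A      1      10     1    0000    0.000000e+00    0.00     0.979,0.007,0.011,0.000,0.000,0.000,0.003,0.000,0.000
TP          2       A      1      10     0    0000    6.000000e+01    6.72     0.000,0.007,0.000,0.000,0.012,0.072,0.220,0.383,0.306
TP          3       A      1      10     1    0000    6.000000e+01    6.82     0.000,0.002,0.000,0.004,0.017,0.072,0.210,0.392,0.303
TP          4       A      1      10     0    0000    6.000000e+02    7.13     0.000,0.000,0.000,0.000,0.004,0.024,0.134,0.371,0.467
TP          5       A      1      10     1    0000    6.000000e+02    7.17     0.002,0.000,0.007,0.000,0.006,0.027,0.122,0.372,0.464
TP          6       A      1      10     0    0000    inf             7.12     0.001,0.001,0.003,0.001,0.000,0.027,0.126,0.371,0.470
TP          7       A      1      10     1    0000    inf             7.11     0.007,0.000,0.006,0.002,0.008,0.029,0.130,0.359,0.459
TP          8       A      5      14     0    0000    0.000000e+00    0.00     0.984,0.000,0.000,0.003,0.004,0.002,0.000,0.000,0.007
TP          9       A      5      14     1    0000    0.000000e+00    0.00     0.988,0.000,0.000,0.000,0.003,0.000,0.000,0.005,0.004
TP          10      A      5      14     0    0000    6.000000e+01    1.75     0.123,0.284,0.313,0.198,0.068,0.014,0.000,0.000,0.000
TP          11      A      5      14     1    0000    6.000000e+01    1.80     0.118,0.289,0.310,0.183,0.082,0.015,0.003,0.000,0.000
TP          12      A      5      14     0    0000    6.000000e+02    6.83     0.001,0.001,0.000,0.002,0.011,0.066,0.209,0.395,0.315
TP          13      A      5      14     1    0000    6.000000e+02    6.77     0.013,0.000,0.001,0.000,0.006,0.068,0.209,0.392,0.311
TP          14      A      5      14     0    0000    inf             7.18     0.000,0.000,0.000,0.001,0.006,0.023,0.127,0.372,0.471
TP          15      A      5      14     1    0000    inf             7.18     0.000,0.000,0.006,0.000,0.003,0.025,0.125,0.370,0.471
TP          16      A      9      18     0    0000    0.000000e+00    0.00     0.985,0.006,0.000,0.000,0.003,0.000,0.000,0.000,0.006
TP          17      A      9      18     1    0000    0.000000e+00    0.00     0.994,0.000,0.000,0.000,0.000,0.000,0.006,0.000,0.000
TP          18      A      9      18     0    0000    6.000000e+01    0.22     0.792,0.173,0.020,0.008,0.000,0.002,0.001,0.004,0.000
TP          19      A      9      18     1    0000    6.000000e+01    0.23     0.797,0.167,0.025,0.005,0.000,0.000,0.003,0.003,0.000
TP          20      A      9      18     0    0000    6.000000e+02    1.83     0.117,0.284,0.312,0.193,0.073,0.012,0.006,0.003,0.000
TP          21      A      9      18     1    0000    6.000000e+02    1.89     0.109,0.291,0.311,0.194,0.068,0.014,0.008,0.002,0.003
TP          22      A      9      18     0    0000    inf             7.10     0.009,0.001,0.000,0.002,0.009,0.035,0.121,0.362,0.461
TP          23      A      9      18     1    0000    inf             7.21     0.000,0.000,0.000,0.000,0.013,0.026,0.127,0.370,0.464
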