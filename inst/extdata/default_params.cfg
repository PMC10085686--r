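sX_regulator_total = 10
sX_inducer_Kd = 0.5
sX_dna_Kd = 0.00025000000000000001
sX_dna_copies = 0.10000000000000001
sX_max_rate = 119
sX_hill = 1
sY_regulator_total = 1
sY_inducer_Kd = 4000
sY_dna_Kd = 4
sY_dna_copies = 0.20000000000000001
sY_max_rate = 96
sY_hill = 1
delta_X = 6
delta_Y = 6
a5 = 14.199999999999999
b5 = 30
k5 = 40
a6 = 14.199999999999999
b6 = 30
k6 = 40
R_tot = 10
d0 = 1
a = 121
b = 10
k = 110
gamma = 1
protease_tag = TRUE
gfp_per_uM = 12175718.800000001
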