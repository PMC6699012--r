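# Synthetic age-indexed background schedules (linearly interpolated between
# pivot ages): annual_cost = age-appropriate background healthcare cost,
# 2017 US$ per person-year, third-party-payer perspective;
# baseline_utility = population-norm health-related quality-of-life weight,
# declining with age. Levels were calibrated once with calibrate_background
# (cost multiplier 1.291362, utility multiplier 1.033411 on the original
# shape) so the full model reproduces the outpatient-NOM lifetime discounted
# cost and QALY anchors at start age 20; the age gradient (shape) is never
# altered by calibration.
age	annual_cost	baseline_utility
0	2582.72	0.971407
20	3228.41	0.961072
30	4519.77	0.950738
40	6456.81	0.940404
50	9685.22	0.919736
60	14204.98	0.899068
70	20661.79	0.868065
80	28409.97	0.816395
90	36158.14	0.764724
100	41323.59	0.723388
110	43906.31	0.702720
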