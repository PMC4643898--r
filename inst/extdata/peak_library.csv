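metabolite,role,center_ppm,rel_intensity,hwhm_ppm,base_conc
ethanol,panel,1.170,0.75,0.0012,1.0
ethanol,panel,1.182,1.50,0.0012,1.0
ethanol,panel,1.194,0.75,0.0012,1.0
ethanol,panel,3.634,0.17,0.0012,1.0
ethanol,panel,3.646,0.50,0.0012,1.0
ethanol,panel,3.658,0.50,0.0012,1.0
ethanol,panel,3.670,0.17,0.0012,1.0
glucose,panel,3.240,1.00,0.0020,3.0
glucose,panel,3.400,1.50,0.0020,3.0
glucose,panel,3.460,1.50,0.0020,3.0
glucose,panel,3.530,1.20,0.0020,3.0
glucose,panel,3.720,1.50,0.0020,3.0
glucose,panel,3.840,1.00,0.0020,3.0
glucose,panel,3.890,0.80,0.0020,3.0
glucose,panel,5.233,0.40,0.0015,3.0
hippurate,panel,3.970,2.00,0.0013,4.0
hippurate,panel,7.550,1.00,0.0013,4.0
hippurate,panel,7.640,2.00,0.0013,4.0
hippurate,panel,7.840,2.00,0.0013,4.0
unknown_1.42,panel,1.420,1.00,0.0013,1.0
methionine,panel,2.130,3.00,0.0012,0.8
methionine,panel,2.640,1.00,0.0012,0.8
glutamine,panel,2.440,1.00,0.0013,1.5
glutamine,panel,2.460,1.00,0.0013,1.5
arginine,panel,1.660,0.80,0.0015,0.8
arginine,panel,1.680,1.20,0.0015,0.8
arginine,panel,1.700,1.20,0.0015,0.8
arginine,panel,1.720,0.80,0.0015,0.8
arginine,panel,1.900,1.50,0.0015,0.8
arginine,panel,3.230,1.50,0.0015,0.8
phenylalanine,panel,7.320,2.00,0.0013,0.6
phenylalanine,panel,7.370,1.00,0.0013,0.6
phenylalanine,panel,7.420,2.00,0.0013,0.6
creatinine,background,3.050,3.00,0.0013,10.0
creatinine,background,4.060,2.00,0.0013,10.0
citrate,background,2.540,2.00,0.0015,5.0
citrate,background,2.660,2.00,0.0015,5.0
lactate,background,1.325,1.50,0.0012,2.0
lactate,background,1.340,1.50,0.0012,2.0
lactate,background,4.120,1.00,0.0012,2.0
alanine,background,1.470,1.50,0.0012,1.5
alanine,background,1.485,1.50,0.0012,1.5
glycine,background,3.560,2.00,0.0012,3.0
taurine,background,3.260,2.00,0.0015,2.0
taurine,background,3.430,2.00,0.0015,2.0
urea,background,5.790,4.00,0.0100,8.0
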