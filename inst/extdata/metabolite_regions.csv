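metabolite,low_ppm,high_ppm,mode
ethanol,1.150,1.215,integral
glucose,5.200,5.270,integral
hippurate,7.800,7.880,integral
unknown_1.42,1.400,1.450,integral
methionine,2.100,2.160,integral
glutamine,2.410,2.490,integral
arginine,1.630,1.760,integral
phenylalanine,7.290,7.450,integral
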