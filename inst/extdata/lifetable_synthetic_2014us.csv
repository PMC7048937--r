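age,sex,annual_mortality
55,male,0.00744850874083049
56,male,0.00808163198380108
57,male,0.00876857070242417
58,male,0.00951389921213022
59,male,0.0103225806451613
60,male,0.0112
61,male,0.012152
62,male,0.01318492
63,male,0.0143056382
64,male,0.015521617447
65,male,0.016840954929995
66,male,0.0182724360990446
67,male,0.0198255931674634
68,male,0.0215107685866977
69,male,0.0233391839165671
70,male,0.0253230145494752
55,female,0.00438929979370368
56,female,0.00476239027616849
57,female,0.00516719344964281
58,female,0.00560640489286245
59,female,0.00608294930875576
60,female,0.0066
61,female,0.007161
62,female,0.007769685
63,female,0.008430108225
64,female,0.009146667424125
65,female,0.00992413415517562
66,female,0.0107676855583656
67,female,0.0116829388308266
68,female,0.0126759886314469
69,female,0.0137534476651199
70,female,0.0149224907166551
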