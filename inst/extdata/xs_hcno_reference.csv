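# Elemental mass attenuation coefficients (cm^2/g) for H, C, N, O,
# 0.015-15 MeV.
# total_mu_rho_cm2_g: total attenuation (with coherent scattering),
#   transcribed from the standard NIST/XCOM photon cross-section
#   tabulation for these elements.
# compton_mu_rho_cm2_g: incoherent (Compton) partial coefficient computed
#   from the Klein-Nishina per-electron cross section times N_A*Z/A.
#   Accurate in the Compton-dominated regime (>~0.1 MeV for low-Z
#   elements); overestimates below ~50 keV where the incoherent
#   scattering function suppresses forward scattering.
element,Z,energy_MeV,total_mu_rho_cm2_g,compton_mu_rho_cm2_g
H,1,0.015,0.37640,0.375764
H,1,0.020,0.36950,0.369207
H,1,0.030,0.35700,0.356964
H,1,0.040,0.34580,0.345758
H,1,0.050,0.33550,0.335464
H,1,0.060,0.32600,0.325972
H,1,0.080,0.30910,0.309044
H,1,0.100,0.29440,0.294385
H,1,0.150,0.26510,0.265025
H,1,0.200,0.24290,0.242847
H,1,0.300,0.21120,0.211163
H,1,0.400,0.18930,0.189195
H,1,0.500,0.17290,0.172758
H,1,0.600,0.15990,0.159812
H,1,0.800,0.14050,0.140373
H,1,1.000,0.12630,0.126183
H,1,1.250,0.11290,0.112807
H,1,1.500,0.10270,0.102506
H,1,2.000,0.08769,0.087440
H,1,3.000,0.06921,0.068759
H,1,4.000,0.05806,0.057338
H,1,5.000,0.05049,0.049507
H,1,6.000,0.04498,0.043750
H,1,8.000,0.03746,0.035777
H,1,10.000,0.03254,0.030462
H,1,15.000,0.02539,0.022530
C,6,0.015,0.80710,0.189212
C,6,0.020,0.44200,0.185910
C,6,0.030,0.25620,0.179745
C,6,0.040,0.20760,0.174103
C,6,0.050,0.18710,0.168919
C,6,0.060,0.17530,0.164140
C,6,0.080,0.16100,0.155616
C,6,0.100,0.15140,0.148234
C,6,0.150,0.13470,0.133450
C,6,0.200,0.12290,0.122283
C,6,0.300,0.10660,0.106329
C,6,0.400,0.09546,0.095267
C,6,0.500,0.08715,0.086990
C,6,0.600,0.08058,0.080472
C,6,0.800,0.07076,0.070683
C,6,1.000,0.06361,0.063538
C,6,1.250,0.05690,0.056803
C,6,1.500,0.05179,0.051616
C,6,2.000,0.04442,0.044029
C,6,3.000,0.03562,0.034623
C,6,4.000,0.03047,0.028872
C,6,5.000,0.02708,0.024928
C,6,6.000,0.02469,0.022030
C,6,8.000,0.02154,0.018015
C,6,10.000,0.01959,0.015339
C,6,15.000,0.01698,0.011345
N,7,0.015,1.23600,0.189290
N,7,0.020,0.61780,0.185987
N,7,0.030,0.30660,0.179820
N,7,0.040,0.22880,0.174175
N,7,0.050,0.19800,0.168989
N,7,0.060,0.18170,0.164208
N,7,0.080,0.16390,0.155680
N,7,0.100,0.15290,0.148296
N,7,0.150,0.13530,0.133506
N,7,0.200,0.12330,0.122334
N,7,0.300,0.10680,0.106373
N,7,0.400,0.09557,0.095307
N,7,0.500,0.08719,0.087027
N,7,0.600,0.08063,0.080505
N,7,0.800,0.07081,0.070713
N,7,1.000,0.06364,0.063564
N,7,1.250,0.05693,0.056826
N,7,1.500,0.05180,0.051637
N,7,2.000,0.04450,0.044048
N,7,3.000,0.03579,0.034637
N,7,4.000,0.03073,0.028884
N,7,5.000,0.02742,0.024939
N,7,6.000,0.02511,0.022039
N,7,8.000,0.02209,0.018022
N,7,10.000,0.02024,0.015345
N,7,15.000,0.01782,0.011350
O,8,0.015,1.83600,0.189397
O,8,0.020,0.86510,0.186092
O,8,0.030,0.37790,0.179921
O,8,0.040,0.25850,0.174273
O,8,0.050,0.21320,0.169084
O,8,0.060,0.19070,0.164300
O,8,0.080,0.16780,0.155768
O,8,0.100,0.15510,0.148379
O,8,0.150,0.13610,0.133581
O,8,0.200,0.12370,0.122402
O,8,0.300,0.10700,0.106433
O,8,0.400,0.09566,0.095360
O,8,0.500,0.08729,0.087075
O,8,0.600,0.08070,0.080550
O,8,0.800,0.07087,0.070752
O,8,1.000,0.06372,0.063600
O,8,1.250,0.05697,0.056858
O,8,1.500,0.05185,0.051666
O,8,2.000,0.04459,0.044072
O,8,3.000,0.03597,0.034657
O,8,4.000,0.03100,0.028900
O,8,5.000,0.02777,0.024953
O,8,6.000,0.02552,0.022051
O,8,8.000,0.02263,0.018033
O,8,10.000,0.02089,0.015354
O,8,15.000,0.01866,0.011356
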