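index,enthalpy,polarity,molar_volume,complexity,refractivity
ABC,21.4533,5.14068,51.8856,107.768,10.49394
RA,22.2725,5.34215,53.57962,125.620,11.19653
S,22.1989,5.28520,53.30246,122.563,11.06695
GA,22.1199,5.23301,53.02684,118.977,10.95059
M1,21.2492,5.11913,51.52025,104.072,10.48881
M2,21.2992,5.17904,51.99331,102.996,10.64628
HM,21.0026,5.19160,51.74557,101.693,10.61813
F,21.0026,5.19160,51.64475,101.327,10.63600
H,22.7532,5.45760,54.81297,133.606,11.66503
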