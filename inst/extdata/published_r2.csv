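index,enthalpy,polarity,molar_volume,complexity,refractivity
ABC,0.699,0.386,0.736,0.893,0.846
RA,0.552,0.765,0.710,0.855,0.824
S,0.555,0.770,0.713,0.862,0.828
GA,0.559,0.774,0.716,0.870,0.832
M1,0.593,0.784,0.732,0.900,0.846
M2,0.591,0.779,0.727,0.902,0.841
HM,0.602,0.778,0.730,0.905,0.842
F,0.674,0.341,0.731,0.905,0.842
H,0.703,0.439,0.697,0.835,0.809
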