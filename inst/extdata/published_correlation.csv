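index,enthalpy,polarity,molar_volume,complexity,refractivity
ABC,0.836,0.621,0.858,0.945,0.920
RA,0.743,0.875,0.843,0.924,0.908
S,0.745,0.877,0.845,0.928,0.910
GA,0.747,0.880,0.846,0.932,0.912
M1,0.770,0.886,0.856,0.949,0.920
M2,0.769,0.883,0.853,0.950,0.971
HM,0.776,0.882,0.854,0.951,0.918
F,0.821,0.584,0.855,0.952,0.917
H,0.838,0.8663,0.835,0.914,0.900
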