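quantity,location_a,value_a,location_b,value_b,default_choice,note
monobenzone polarity,Table 2,23.50,Table 15,35.50,Table 2,conflicting duplicated observation; which value fed the published polarity statistics is undeterminable
azathioprine refractivity,Table 2,69.94,Table 18,59.94,Table 2,conflicting duplicated observation; which value fed the published refractivity statistics is undeterminable
fluticasone molar volume,Table 2,323.20,Table 16,336.6,Table 2,conflicting duplicated observation; which value fed the published molar-volume statistics is undeterminable
psoralen hyper-Zagreb HM,Theorem 1 proof,336,Theorem 1 statement / Table 1,386,Definition formula,definition evaluates to 386 on the printed partition; the proof figure is a typo
azathioprine geometric-arithmetic GA,Theorem 2 statement / Table 1,19.68,Definition 4 on printed partition,19.63,Definition formula,formula value 19.6270 rounds to 19.63; printed 19.68 treated as a typo
azathioprine atom-bond connectivity ABC,Theorem 2 statement / Table 1,14.08,Definition 1 on printed partition,14.09,Definition formula,formula value 14.0898 rounds to 14.09; printed 14.08 treated as rounding error
azathioprine harmonic H,Theorem 2 proof,9.60,Theorem 2 statement / Table 1,8.60,Definition formula,formula gives exactly 8.60; the proof figure is a typo
psoralen Randic RA,Table 1,6.82,Definition 2 on printed partition,6.83,Definition formula,formula value 6.8265 rounds half-up to 6.83; printed 6.82 treated as truncation
correlation of harmonic index with polarity,Table 12,0.8663,Table 10,0.663,Table 10,recomputation from Table 1/Table 2 supports neither cell exactly; the two printed values conflict
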