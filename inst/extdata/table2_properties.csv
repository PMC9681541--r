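name,refractivity,enthalpy,molar_volume,polarity,complexity,boiling_point
Fluticasone propionate,121.65,98,377,48.01,984,568.3
Clobetasone,104.72,95.3,309.1,40.5,850,549
Beclomethasone dipropionate,134.79,103.5,302.6,41.6,1050,600.2
Desonide,112.06,99.6,320.1,43.3,873,580.1
Clobetasol propionate,119.32,98.1,364.1,46.7,929,569
Azathioprine,69.94,96.9,145.4,27.3,354,685.7
Monobenzone,59.11,62.8,172.6,23.5,167,359.1
Betamethasone valerate,NA,102.3,382.4,49,957,598.9
Psoralen,NA,60.9,134,19.8,284,362.6
Hydrocortisone valerate,120.38,101.8,367.6,47.2,832,595.3
Fluticasone,107.87,95.9,323.2,42.4,861,553.2
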