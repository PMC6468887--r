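"sex","age_years","cut_minus2sd","cut_plus1sd","cut_plus2sd"
"male",5,11.8,17.42,19.84
"male",6,11.87,17.54,19.97
"male",7,11.95,17.65,20.1
"male",8,12.14,17.94,20.43
"male",9,12.34,18.22,20.75
"male",10,12.68,18.73,21.33
"male",11,13.03,19.25,21.92
"male",12,13.53,19.99,22.76
"male",13,14.03,20.73,23.6
"male",14,14.65,21.64,24.64
"male",15,15.27,22.55,25.68
"male",16,15.73,23.23,26.46
"male",17,16.19,23.92,27.24
"male",18,16.58,24.48,27.88
"female",5,11.8,17.42,19.84
"female",6,11.84,17.48,19.91
"female",7,11.87,17.54,19.97
"female",8,12.11,17.88,20.36
"female",9,12.34,18.22,20.75
"female",10,12.72,18.79,21.4
"female",11,13.11,19.36,22.05
"female",12,13.72,20.27,23.09
"female",13,14.34,21.18,24.12
"female",14,14.96,22.09,25.16
"female",15,15.58,23,26.2
"female",16,15.96,23.57,26.85
"female",17,16.35,24.14,27.49
"female",18,16.65,24.6,28.01
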