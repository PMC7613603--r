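outcome,cough,difficult_breathing,resp_rate,oxygen_sat,avpu,indrawing,diagnosis,treatment,dose
cough,1.05,,,,,,,,
difficult_breathing,0.17,0.71,,,,,,,
resp_rate,-0.29,-0.60,2.47,,,,,,
oxygen_sat,-0.30,-0.78,0.89,2.23,,,,,
avpu,-0.12,-0.24,-0.12,0.22,1.76,,,,
indrawing,-0.30,0.06,-0.52,-0.50,-0.26,1.82,,,
diagnosis,-0.54,-0.65,0.40,0.24,-0.07,0.35,2.14,,
treatment,-0.45,-0.55,0.23,0.26,-0.22,0.52,0.77,0.56,
dose,-0.47,-0.76,0.63,0.64,-0.18,0.15,0.74,0.80,0.67
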