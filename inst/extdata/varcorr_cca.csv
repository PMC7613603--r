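outcome,cough,difficult_breathing,resp_rate,oxygen_sat,avpu,indrawing,diagnosis,treatment,dose
cough,1.49,,,,,,,,
difficult_breathing,0.07,1.92,,,,,,,
resp_rate,-0.29,-0.43,2.71,,,,,,
oxygen_sat,-0.17,-0.47,0.63,7.38,,,,,
avpu,-0.14,-0.19,-0.20,0.09,2.26,,,,
indrawing,-0.22,-0.11,-0.54,-0.39,-0.19,2.33,,,
diagnosis,-0.49,-0.53,0.48,0.29,-0.06,0.04,2.64,,
treatment,-0.48,-0.42,0.07,0.16,-0.38,0.66,0.64,1.81,
dose,-0.54,-0.64,0.57,0.69,-0.21,0.19,0.62,0.73,1.30
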