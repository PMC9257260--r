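label,x,y
Fp1,-0.027082,0.100420
AF3,-0.027798,0.086214
F3,-0.038001,0.063584
F7,-0.062488,0.063554
FC5,-0.059304,0.038607
FC1,-0.023897,0.041292
C3,-0.045401,0.015793
T7,-0.071360,0.012343
CP5,-0.058644,-0.009601
CP1,-0.024149,-0.006984
P3,-0.037350,-0.030002
P7,-0.059013,-0.033385
PO3,-0.027095,-0.047254
O1,-0.023942,-0.061094
Oz,-0.001526,-0.061303
Pz,-0.001110,-0.029356
Fp2,0.024915,0.101158
AF4,0.027004,0.086630
Fz,-0.000858,0.065129
F4,0.036975,0.064307
F8,0.062352,0.065032
FC6,0.058474,0.039134
FC2,0.022157,0.041348
Cz,-0.000880,0.017693
C4,0.044106,0.015915
T8,0.068862,0.012619
CP6,0.058526,-0.009679
CP2,0.023523,-0.007033
P4,0.036325,-0.030026
P8,0.056003,-0.033319
PO4,0.024282,-0.047392
O2,0.020939,-0.060880
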