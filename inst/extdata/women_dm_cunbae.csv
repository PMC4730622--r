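"category","N","n","cOR","aOR"
"C1",303,10,1,1
"C2",402,23,1.78,1.64
"C3",464,36,2.46,1.86
"C4",389,61,5.45,3.47
"C5",297,81,10.99,6.49
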