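"category","N","n","cOR","aOR"
"C1",303,9,1,1
"C2",402,36,3.21,2.97
"C3",464,108,9.91,7.82
"C4",389,165,24.06,16.1
"C5",297,162,39.2,23.3
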