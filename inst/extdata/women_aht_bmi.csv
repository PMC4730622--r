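"category","N","n","cOR","aOR"
"C1",895,119,1,1
"C2",565,180,3.05,1.99
"C3",259,110,4.81,2.73
"C4",86,45,7.15,4.93
"C5",50,26,7.06,7.71
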