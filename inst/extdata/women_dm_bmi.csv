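"category","N","n","cOR","aOR"
"C1",895,50,1,1
"C2",565,76,2.63,1.78
"C3",259,45,3.55,2.09
"C4",86,21,5.46,3.44
"C5",50,19,10.36,8.13
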