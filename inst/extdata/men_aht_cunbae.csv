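"category","N","n","cOR","aOR"
"C1",258,21,1,1
"C2",521,79,2.02,1.67
"C3",631,208,5.55,3.8
"C4",415,199,10.4,6.8
"C5",208,121,15.7,11.24
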