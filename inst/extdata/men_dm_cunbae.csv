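"category","N","n","cOR","aOR"
"C1",258,9,1,1
"C2",521,35,1.99,1.66
"C3",631,95,4.9,3.49
"C4",415,87,7.34,4.91
"C5",208,65,12.58,8.34
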