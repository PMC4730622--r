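"category","N","n","cOR","aOR"
"C1",749,152,1,1
"C2",849,254,1.68,1.33
"C3",328,169,4.17,3.93
"C4",74,37,3.93,4.5
"C5",33,16,3.7,8.66
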