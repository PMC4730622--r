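"category","N","n","cOR","aOR"
"C1",749,73,1,1
"C2",849,113,1.42,1.13
"C3",328,79,2.94,2.37
"C4",74,21,2.97,3.19
"C5",33,5,,
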