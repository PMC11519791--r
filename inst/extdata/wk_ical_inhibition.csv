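# Mean percent inhibition of I_Ca-L by the aqueous extract (WK), mg/mL
concentration,response
1,4.072
10,13.225
20,40.819
50,80.512
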