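# Mean percent inhibition of I_Ca-L by dioscin, umol/L
concentration,response
1,15.065
3,28.270
10,60.040
30,93.574
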