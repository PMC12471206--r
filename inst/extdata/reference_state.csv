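variable,value
a,5.32e9
mq,5.44e6
cq,2.61e6
q,3.20e9
mL,5.13e4
mS,1.22e8
cL,1.8e5
O1,2.78e7
bL,2.83e3
bS,5.64e3
L,1.07e3
S,1.34e4
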