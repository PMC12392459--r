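# synthetic example: methanol-like fragment, three fictitious conformer charge sets
atom,type,conf1,conf2,conf3
C1,c3,0.116,0.121,0.112
H11,h1,0.028,0.030,0.027
H12,h1,0.029,0.027,0.031
H13,h1,0.030,0.028,0.026
O1,oh,-0.598,-0.611,-0.590
H2,ho,0.395,0.405,0.394
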