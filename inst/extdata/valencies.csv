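element,charge,valences
H,0,1
H,1,0
C,0,4
C,-1,3
C,1,3
N,0,3
N,1,4
N,-1,2
O,0,2
O,1,3
O,-1,1
F,0,1
F,-1,0
B,0,3
Al,0,3
Si,0,4
P,0,3|5
S,0,4
Cl,0,1
As,0,3
Br,0,1
I,0,1
Hg,0,1|2
Bi,0,3|5
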