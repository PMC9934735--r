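elem1,elem2,order,length_pm
H,H,1,74
H,C,1,109
H,N,1,101
H,O,1,96
H,F,1,92
H,B,1,119
H,Si,1,148
H,P,1,144
H,As,1,152
H,S,1,134
H,Cl,1,127
H,Br,1,141
H,I,1,161
C,C,1,154
C,N,1,147
C,O,1,143
C,F,1,135
C,Cl,1,177
C,Br,1,194
C,I,1,214
C,S,1,182
C,Si,1,185
C,P,1,184
C,B,1,156
N,N,1,145
N,O,1,140
N,F,1,136
N,Cl,1,175
N,Br,1,214
N,S,1,168
N,I,1,222
N,P,1,177
O,O,1,148
O,F,1,142
O,Br,1,172
O,S,1,151
O,P,1,163
O,Si,1,163
O,Cl,1,164
O,I,1,194
F,F,1,142
F,S,1,158
F,Si,1,160
F,Cl,1,166
F,Br,1,178
F,P,1,156
F,I,1,187
B,B,1,172
B,N,1,158
B,O,1,154
B,F,1,150
B,Cl,1,175
B,Br,1,187
Si,Si,1,233
Si,S,1,200
Si,Cl,1,202
Si,Br,1,215
Si,I,1,243
Si,P,1,227
P,P,1,221
P,S,1,210
P,Cl,1,203
P,Br,1,222
S,S,1,204
S,Cl,1,207
S,Br,1,225
Cl,Cl,1,199
Br,Br,1,228
I,I,1,266
As,As,1,246
C,C,2,134
C,N,2,129
C,O,2,120
C,S,2,160
N,N,2,125
N,O,2,121
O,O,2,121
O,P,2,150
P,S,2,186
C,C,3,120
C,N,3,116
C,O,3,113
N,N,3,110
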