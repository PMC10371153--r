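>TOY.0002 cMYC
A [  8 70  3  4  6  5 12 10 ]
C [ 76 10 91  4  6  5 12 60 ]
G [  8 10  3 88  6 85 12 15 ]
T [  8 10  3  4 82  5 64 15 ]
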