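>TOY.0001 P53_half
A [ 10  5 15  2 80 60  4 10  6 12 ]
C [ 10  5 10 94  6 15  4 15 82 64 ]
G [ 70 85 60  2  6 10 88  5  6 12 ]
T [ 10  5 15  2  8 15  4 70  6 12 ]
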