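MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF cMYC
letter-probability matrix: alength= 4 w= 8 nsites= 100
 0.08 0.76 0.08 0.08
 0.70 0.10 0.10 0.10
 0.03 0.91 0.03 0.03
 0.04 0.04 0.88 0.04
 0.06 0.06 0.06 0.82
 0.05 0.05 0.85 0.05
 0.12 0.12 0.12 0.64
 0.10 0.60 0.15 0.15
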