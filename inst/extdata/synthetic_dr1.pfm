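>SYN_DR1 synthetic nuclear-receptor direct-repeat motif (consensus AGGTCAAAGGTCA)
A [ 97 1 1 1 1 97 97 97 1 1 1 1 97 ]
C [ 1 1 1 1 97 1 1 1 1 1 1 97 1 ]
G [ 1 97 97 1 1 1 1 1 97 97 1 1 1 ]
T [ 1 1 1 97 1 1 1 1 1 1 97 1 1 ]
>SYN_EBOX synthetic E-box-like control motif (consensus CACGTGTC)
A [ 1 97 1 1 1 1 1 1 ]
C [ 97 1 97 1 1 1 1 97 ]
G [ 1 1 1 97 1 97 1 1 ]
T [ 1 1 1 1 97 1 97 1 ]
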