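>SYN0001 synthetic_example_motif
A [ 5 5 85 5 5 5 5 85 5 5 85 5 ]
C [ 5 5 5 85 5 5 85 5 5 85 5 5 ]
G [ 5 85 5 5 5 85 5 5 5 5 5 85 ]
T [ 85 5 5 5 85 5 5 5 85 5 5 5 ]
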