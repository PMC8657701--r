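subgenome	motif
A	QPFPQPQT
B	QPYPQPQS
D	QPIPQPQM
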