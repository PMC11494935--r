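# element  atom-typing radius (angstrom)
H 0.40
C 0.80
N 0.75
O 0.75
F 0.70
S 1.05
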