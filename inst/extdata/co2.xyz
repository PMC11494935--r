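3
CO2 equilibrium geometry (CCSD-optimized)
O       1.1570000000     0.0000000000     0.0000000000
C       0.0000000000     0.0000000000     0.0000000000
O      -1.1570000000     0.0000000000     0.0000000000
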