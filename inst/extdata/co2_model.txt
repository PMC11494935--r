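# ffft flexibility model
subdomain = CO2_ground_state

[term]
kind = stretch_manz
atoms = 1 2
eq = 1.157
k = 30.58
gamma = 1.203

[term]
kind = stretch_manz
atoms = 3 2
eq = 1.157
k = 30.58
gamma = 1.203

[term]
kind = bend_new
atoms = 1 2 3
eq = 180
k = 5.17
nu = 2
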