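# model (c): information drift, small mutation scale
b_eta: 1
a_zeta: 1
b_zeta: 1
eps_eta: 0.005
eps_zeta: 0.005
g: 0.002
rho0: 1.0e+18
d: 500
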