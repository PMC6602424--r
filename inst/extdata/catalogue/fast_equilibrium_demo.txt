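# fast A <-> B equilibrium fed by a slow inflow
# at quasi-equilibrium: kf*A = kr*B, total T = A + B obeys dT/dt = v0
model fast_equilibrium_demo
var A = 1
var B = 2
const kf = 2
const kr = 1
const v0 = 1
fast J1: A <-> B; kf*A - kr*B
J2:  -> A; v0
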