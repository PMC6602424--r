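# reversible dimerization with explicit combinatorial propensities
model dimerization
var A = 100
var B = 0
const c1 = 0.005
const c2 = 0.1
J1: 2 A -> B; c1*A*(A - 1)/2
J2: B -> 2 A; c2*B
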