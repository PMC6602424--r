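# classic stiff reaction system; A + B + C = 1 is conserved
model robertson
var A = 1
var B = 0
var C = 0
const p1 = 0.04
const p2 = 30000000
const p3 = 10000
J1: A -> B; p1*A
J2: 2 B -> B + C; p2*B^2
J3: B + C -> A + C; p3*B*C
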