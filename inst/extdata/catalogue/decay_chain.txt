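# monolithic two-step decay chain A -> B -> C
model decay_chain
var A = 1
var B = 0
var C = 0
const k1 = 1
const k2 = 0.5
J1: A -> B; k1*A
J2: B -> C; k2*B
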