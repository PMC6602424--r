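# first-order decay, closed form A(t) = A0 * exp(-k*t)
model decay
var A = 1
const k = 1
J1: A -> ; k*A
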