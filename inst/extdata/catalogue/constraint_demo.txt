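# decay with a constraint; violated at t = ln 4
model constraint_demo
var A = 1
const k = 1
J1: A -> ; k*A
constraint C1 (A > 0.25): A dropped below 0.25
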