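# decay with a threshold event; fires at t = ln 2
model event_demo
var A = 1
const k = 1
const y = 0
J1: A -> ; k*A
at E1 (A <= 0.5): y = 1
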