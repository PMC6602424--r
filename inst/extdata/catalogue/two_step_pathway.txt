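# linear two-step pathway: steady state S* = k1*S0/(k1 + k2)
model two_step_pathway
var S = 0
const k1 = 1
const k2 = 1
const S0 = 2
J1:  -> S; k1*(S0 - S)
J2: S -> ; k2*S
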