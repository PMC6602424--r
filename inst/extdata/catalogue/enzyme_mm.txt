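# mass-action enzyme mechanism E + S <-> ES -> E + P
# conserved moieties: E + ES and S + ES + P
model enzyme_mm
var E = 1
var S = 10
var ES = 0
var P = 0
const k1 = 2
const km1 = 1
const k2 = 1.5
J1: E + S <-> ES; k1*E*S - km1*ES
J2: ES -> E + P; k2*ES
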