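# immigration-death process; stationary law Poisson(lambda/mu)
model immigration_death
var X = 0
const lambda = 10
const mu = 1
J1:  -> X; lambda
J2: X -> ; mu*X
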