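# logistic growth, closed form x(t) = 1/(1 + (1/x0 - 1) exp(-t))
model logistic
var x = 0.5
x' = x*(1 - x)
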