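# the decay chain split into two modules sharing species B
module M1
  var A = 1
  var B = 0
  const k1 = 1
  J1: A -> B; k1*A
end
module M2
  var B = 0
  var C = 0
  const k2 = 0.5
  J2: B -> C; k2*B
end
connect M1.B = M2.B master M1.B
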