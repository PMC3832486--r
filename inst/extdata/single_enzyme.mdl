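# Single-molecule enzyme cycle E + S <-> ES -> E + P with one enzyme copy
# and the substrate clamped (fixed $S), so E + ES = 1 is conserved and the
# product waiting-time distribution is an exact two-phase (hypoexponential
# with reset) law. Effective rates: k1*S = 1 / min, km1 = 0.5, k2 = 1.
# Package-chosen defaults.
E = 1
ES = 0
P = 0
$S = 100
k1 : 0.01
km1 : 0.5
k2 : 1
Bind: E + $S > ES, k1
Unbind: ES > E + $S, km1
Cat: ES > E + P, k2
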