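# Immigration-death model: zero-order mRNA synthesis, first-order decay.
# ksyn = 10 / min, kd = 0.2 / min; stationary law Poisson(ksyn / kd) = Poisson(50).
mRNA = 50
ksyn : 10
kd : 0.2
Rsyn: $pool > mRNA, ksyn
Rdeg: mRNA > $pool, kd
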