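# Two-state (telegraph) gene, non-bursty parameter set: short ON and OFF
# lifetimes (1 min) average out the switching, giving a unimodal mRNA
# distribution. Package-chosen defaults.
Goff = 1
Gon = 0
mRNA = 0
kon : 1
koff : 1
ksyn : 1
kd : 0.05
Ron: Goff > Gon, kon
Roff: Gon > Goff, koff
Rsyn: Gon > Gon + mRNA, ksyn
Rdeg: mRNA > $pool, kd
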