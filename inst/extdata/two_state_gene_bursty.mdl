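# Two-state (telegraph) gene: transcription only while ON.
# Bursty parameter set: long ON and OFF lifetimes (1/kon = 1/koff = 100 min)
# produce transcription bursts, a bimodal mRNA distribution and two time
# scales in the synthesis waiting times. Package-chosen defaults.
Goff = 1
Gon = 0
mRNA = 0
kon : 0.01
koff : 0.01
ksyn : 1
kd : 0.05
Ron: Goff > Gon, kon
Roff: Gon > Goff, koff
Rsyn: Gon > Gon + mRNA, ksyn
Rdeg: mRNA > $pool, kd
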