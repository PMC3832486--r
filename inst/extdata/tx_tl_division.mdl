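# Transcription-translation network for cell-division case studies:
# transcription-factor synthesis, activation/deactivation and turnover,
# TF-dependent transcription with a saturating (Hill, n = 1) rate law (the
# single non-mass-action reaction), translation, and mRNA/protein decay.
# Nine reactions. Structure and parameters are a package reconstruction.
TFi = 10
TFa = 5
mRNA = 5
Protein = 200
ktfs : 0.2
kact : 0.1
kdeact : 0.1
kdtf : 0.005
vmax : 2
Km : 10
ktl : 0.5
kdm : 0.1
kdp : 0.005
R1: $pool > TFi, ktfs
R2: TFi > TFa, kact
R3: TFa > TFi, kdeact
R4: TFi > $pool, kdtf
R5: TFa > $pool, kdtf
R6: $pool > mRNA, vmax*TFa/(Km + TFa)
R7: mRNA > mRNA + Protein, ktl
R8: mRNA > $pool, kdm
R9: Protein > $pool, kdp
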