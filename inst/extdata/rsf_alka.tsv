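# Relative sensitivity factors for Al K-alpha (1486.6 eV) quantification,
# normalized to C1s = 1.  Derived from Scofield-type relative
# photoionization cross sections (J. Electron Spectrosc. Relat. Phenom.
# 8, 129 (1976)); P2p is the 2p3/2 + 2p1/2 total.  Approximate
# transcription; instrument transmission corrections are the user's
# responsibility and can be folded into a custom table.
line	rsf
C1s	1
N1s	1.8
O1s	2.93
P2p	1.19
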