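# cell-free transcription-translation from a hybrid T7 promoter repressed by
# the TetR homodimer (noncompetitive binding block: DNA ~ enzyme, T7 RNAP ~
# substrate, TetR ~ inhibitor).  Kinetic constants below are fitted,
# condition-specific values not reproducible here and are left as UNKNOWN
# placeholders to be supplied by the user.
motif:
  name: txtl
  parameters:
    k_TX: UNKNOWN
    d: UNKNOWN
    k_TL: UNKNOWN
    k_mat: UNKNOWN
    Lm: UNKNOWN
    Cm: UNKNOWN
    Lp: UNKNOWN
    Cp: UNKNOWN
    K_RNAP: UNKNOWN
    K_TetR: UNKNOWN
    K_ribo: UNKNOWN
    DNA0: 6 nM
    RNAP0: UNKNOWN
    TetR0: 0 nM
    Ribo0: UNKNOWN
simulate:
  t_end: 4000
  grid: 500
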