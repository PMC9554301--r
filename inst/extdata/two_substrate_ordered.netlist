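# two-substrate binding with an obligatory order (E binds A before B);
# dissociation constants here are synthetic demonstration values
motif:
  name: two_substrate
  parameters:
    order: A_first
    KdA: 2 mM
    KdB: 4 mM
    k_cat: 500 per_s
    A0: 2 mM
    B0: 2 mM
    E0: 10 nM
simulate:
  t_end: 2000
  grid: 500
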