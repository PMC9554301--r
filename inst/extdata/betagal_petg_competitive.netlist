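# beta-galactosidase competitively inhibited by PETG
motif:
  name: inhibition
  parameters:
    type: competitive
    K_m: 0.167 mM
    k_cat: 2903 per_s
    K_i: 2.33 uM
    E0: 1.0 nM
    S0: 0.6 mM
    I0: 10 uM
simulate:
  t_end: 3000
  grid: 500
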