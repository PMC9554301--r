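# lactate oxidation by lactate dehydrogenase, noncompetitively inhibited by
# oxamate; NAD+ is held constant and its fast binding step is neglected, so
# the single-substrate noncompetitive block applies
motif:
  name: inhibition
  parameters:
    type: noncompetitive
    K_m: 17.1 mM
    k_cat: 215.5 per_s
    K_i: 3.66 mM
    E0: 5.0 nM
    S0: 80 mM
    I0: 7.6 mM
simulate:
  t_end: 360
  grid: 500
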