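# generalized inhibition block, noncompetitive parameterization
# (K_m2 = K_m and K_i2 = K_i are implied by the type)
motif:
  name: inhibition
  parameters:
    type: noncompetitive
    K_m: 2 mM
    k_cat: 500 per_s
    K_i: 3 mM
    E0: 10 nM
    S0: 5 mM
    I0: 3 mM
simulate:
  t_end: 2000
  grid: 500
analysis:
  t_end: 10
  S0_grid: [0.5 mM, 0.75 mM, 1 mM, 1.5 mM, 2 mM, 3 mM, 4 mM, 6 mM,
            8 mM, 12 mM, 16 mM, 20 mM]
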