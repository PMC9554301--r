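# beta-galactosidase / ONPG hydrolysis, quasi-steady-state Michaelis-Menten
# circuit with experimentally measured constants (R = 1/K_m = 5988 Ohm)
motif:
  name: mm_qssa
  parameters:
    K_m: 0.167 mM
    k_cat: 2903 per_s
    E0: 0.3 nM
    S0: 1.2 mM
simulate:
  t_end: 4000
  grid: 500
analysis:
  t_end: 20
  S0_grid: [0.05 mM, 0.1 mM, 0.2 mM, 0.35 mM, 0.5 mM, 0.75 mM, 1 mM,
            1.5 mM, 2 mM, 3 mM, 4 mM, 5 mM]
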