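# product-feedback inhibition: galactose, a co-product of ONPG hydrolysis,
# competitively inhibits beta-galactosidase; newly made product feeds the
# inhibitor pool
motif:
  name: product_feedback
  parameters:
    K_m: 0.167 mM
    k_cat: 2903 per_s
    K_i: 13.7 mM
    E0: 0.7 nM
    S0: 1 mM
    Gal0: 40 mM
simulate:
  t_end: 6000
  grid: 500
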