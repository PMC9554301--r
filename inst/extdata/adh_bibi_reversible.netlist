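# five-step reversible ordered Bi-Bi mechanism of yeast alcohol
# dehydrogenase (NAD+ binds before ethanol; acetaldehyde releases before
# NADH).  The ten literature rate constants require case-specific
# adjustment and are left as UNKNOWN placeholders: supply your own set
# (bimolecular steps per_M_s, unimolecular per_s) before simulating.
motif:
  name: reversible_bibi
  parameters:
    k1: UNKNOWN
    k2: UNKNOWN
    k3: UNKNOWN
    k4: UNKNOWN
    k5: UNKNOWN
    k_m1: UNKNOWN
    k_m2: UNKNOWN
    k_m3: UNKNOWN
    k_m4: UNKNOWN
    k_m5: UNKNOWN
    E0: 3.9 nM
    NAD0: 4 mM
    S0: 20 mM
simulate:
  t_end: 600
  grid: 500
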