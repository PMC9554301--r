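# Shared parameter sets and independent oracles used across test files.

# beta-galactosidase / ONPG constants (M, 1/s)
betagal <- list(K_m = 1.67e-4, k_cat = 2903, E0 = 3e-10, S0 = 1.2e-3)

# generalized-inhibition demo constants
inhib <- list(K_m = 2e-3, k_cat = 500, K_i = 3e-3, E0 = 1e-8, I0 = 3e-3)

# classic free-ligand Michaelis-Menten rate (valid when E0 << S0)
mm_rate <- function(S, K_m, V_max) V_max * S / (K_m + S)

# apparent-parameter closed forms for the four inhibition mechanisms
apparent_params <- function(type, K_m, V_max, I0, K_i, K_i2 = K_i) {
  a  <- 1 + I0 / K_i    # K_m multiplier (EI branch)
  ap <- 1 + I0 / K_i2   # V_max divisor (ESI branch)
  switch(type,
    competitive    = list(K_m = K_m * a, V_max = V_max),
    noncompetitive = list(K_m = K_m, V_max = V_max / a),
    uncompetitive  = list(K_m = K_m / ap, V_max = V_max / ap),
    mixed          = list(K_m = K_m * a / ap, V_max = V_max / ap))
}

# independent tight-binding oracle: ES root of (S0-ES)(E0-ES) = ES*K_m by
# bracketing on the physical branch 0 <= ES <= min(E0, S0)
es_quadratic_oracle <- function(E0, S0, K_m) {
  f <- function(x) (S0 - x) * (E0 - x) - x * K_m
  stats::uniroot(f, c(0, min(E0, S0)), tol = 1e-18)$root
}

# term-by-term evaluator of the exact mass-action ES balance,
# assembled independently of the circuit machinery
es_net_flux_oracle <- function(k_f, k_r, k_cat, E0, S0, ES, P) {
  E_free <- E0 - ES
  S_free <- S0 - ES - P
  k_f * S_free * E_free - ES * k_r - ES * k_cat
}

fast_settings <- function(grid = 150) solver_settings(grid = grid)
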