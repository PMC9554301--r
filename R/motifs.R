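#' @title Circuit motifs for common reaction schemes
#' @description Parameterized factories that assemble [new_circuit()] objects
#'   for the standard enzyme-kinetics building blocks.  All concentrations are
#'   molar and all rate constants 1/s or 1/(M s); use [mM()], [uM()], [nM()]
#'   at the boundary.
#' @name motifs
NULL

.check_pos <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(nm, " must be a single number > 0", call. = FALSE)
  }
}
.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(nm, " must be a single number >= 0", call. = FALSE)
  }
}

#' Production-decay motif (transconductor-fed RC block)
#'
#' A single product node P fed by a constant transconductor current
#' `V_in * k_cat` and drained through a resistor `R = r`, so
#' `dP/dt = V_in * k_cat - P / r` and the steady state is
#' `V_in * k_cat * r`.  With `r = Inf` the decay path is omitted and P grows
#' linearly.
#'
#' @param k_cat production rate constant (1/s).
#' @param r product lifetime (s); resistance of the decay path.  `Inf`
#'   removes the resistor.
#' @param V_in source concentration (M), held constant.
#' @param P0 initial product concentration (M).
#' @return a circuit with one dynamic node `P`.
#' @export
build_production_decay <- function(k_cat, r, V_in, P0 = 0) {
  .check_pos(k_cat = k_cat)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("r must be a single number > 0 (use Inf for no decay)",
         call. = FALSE)
  .check_nonneg(V_in = V_in, P0 = P0)
  circ <- new_circuit("production_decay")
  circ <- add_species(circ, "P", "dynamic", initial_value = P0)
  circ <- add_pool(circ, "S", total = V_in)
  circ <- add_transconductor(circ, "I_in", gain = k_cat, inputs = "S",
                             target = "P", sign = "source")
  if (is.finite(r)) circ <- add_decay(circ, "I_d", node = "P", resistance = r)
  circ
}

#' Exact mass-action Michaelis-Menten circuit
#'
#' The full enzyme-substrate scheme without any steady-state approximation:
#' ES is a dynamic node with capacitor, fed by the bimolecular
#' transconductor `k_f * [E_free][S_free]` and drained by resistors `1/k_r`
#' (dissociation) and `1/k_cat` (catalysis); the catalytic current also
#' charges the product node P.  Enzyme and substrate conservation are
#' bookkept by pools: `E_free = E0 - ES`, `S_free = S0 - ES - P`.
#'
#' @param k_f association rate constant (1/(M s)).
#' @param k_r dissociation rate constant (1/s); 0 removes that resistor.
#' @param k_cat catalytic rate constant (1/s).
#' @param E0,S0 total enzyme and substrate (M).
#' @param K_m optional consistency check: must equal `(k_r + k_cat)/k_f`.
#' @return a circuit with dynamic nodes `ES` and `P`.
#' @export
build_mm_exact <- function(k_f, k_r, k_cat, E0, S0, K_m = NULL) {
  if (missing(k_f) || missing(k_r))
    stop("exact kinetics need k_f and k_r; if only K_m is known use ",
         "build_mm_qssa()", call. = FALSE)
  .check_pos(k_f = k_f, k_cat = k_cat)
  .check_nonneg(k_r = k_r, E0 = E0, S0 = S0)
  if (!is.null(K_m)) {
    km_implied <- (k_r + k_cat) / k_f
    if (abs(km_implied - K_m) > 1e-8 * K_m)
      stop("inconsistent constants: (k_r + k_cat)/k_f = ",
           signif(km_implied, 6), " but K_m = ", signif(K_m, 6),
           call. = FALSE)
  }
  circ <- new_circuit("mm_exact")
  circ <- add_species(circ, "ES", "dynamic", 0)
  circ <- add_species(circ, "P", "dynamic", 0)
  circ <- add_pool(circ, "E_free", total = E0, deductions = c(ES = 1))
  circ <- add_pool(circ, "S_free", total = S0, deductions = c(ES = 1, P = 1))
  circ <- add_transconductor(circ, "I_f", gain = k_f,
                             inputs = c("E_free", "S_free"),
                             target = "ES", sign = "source")
  if (k_r > 0)
    circ <- add_decay(circ, "I_r", node = "ES", resistance = 1 / k_r)
  circ <- add_decay(circ, "I_cat", node = "ES", resistance = 1 / k_cat)
  circ <- add_transconductor(circ, "I_p", gain = k_cat, inputs = "ES",
                             target = "P", sign = "source")
  circ
}

#' Quasi-steady-state Michaelis-Menten circuit
#'
#' The capacitor on ES is removed: ES becomes an algebraic node whose current
#' balance enforces `[E_free][S_free] = [ES] * K_m`.  The forward
#' transconductor gain is fixed at 1 (rates normalized by k_f) and the
#' dissociation resistor is `R = 1/K_m` Ohm with K_m in molar, so
#' K_m = 0.167 mM maps to R = 5988 Ohm.  Both enzyme and substrate pools
#' deduct ES (and the substrate pool deducts P), so the motif stays accurate
#' in the tight-binding regime where E0 is comparable to S0.
#'
#' @param K_m Michaelis constant (M).
#' @param k_cat catalytic rate constant (1/s).
#' @param E0,S0 total enzyme and substrate (M).
#' @return a circuit with algebraic node `ES` and dynamic node `P`.
#' @export
build_mm_qssa <- function(K_m, k_cat, E0, S0) {
  .check_pos(K_m = K_m, k_cat = k_cat)
  .check_nonneg(E0 = E0, S0 = S0)
  circ <- new_circuit("mm_qssa")
  circ <- add_species(circ, "ES", "algebraic", 0)
  circ <- add_species(circ, "P", "dynamic", 0)
  circ <- add_pool(circ, "E_free", total = E0, deductions = c(ES = 1))
  circ <- add_pool(circ, "S_free", total = S0, deductions = c(ES = 1, P = 1))
  circ <- add_transconductor(circ, "I_f", gain = 1,
                             inputs = c("E_free", "S_free"),
                             target = "ES", sign = "source")
  circ <- add_decay(circ, "I_dis", node = "ES", resistance = 1 / K_m)
  circ <- add_transconductor(circ, "I_p", gain = k_cat, inputs = "ES",
                             target = "P", sign = "source")
  circ
}

#' Generalized enzyme-inhibition circuit (QSSA binding block)
#'
#' The three-complex binding block with a catalytic output: algebraic nodes
#' ES, EI and ESI obey the equilibrium balances
#' `[E_free][S_free] = [ES] K_m`, `[E_free][I_free] = [EI] K_i`, and
#' `[EI][S_free] + [ES][I_free] = [ESI] (K_m2 + K_i2)`; only ES drives
#' product formation at `k_cat`.  The four mechanisms are parameter
#' specializations: competitive removes the ESI node entirely, uncompetitive
#' removes the EI branch (exact removal, not a huge resistance),
#' noncompetitive fixes `K_m2 = K_m` and `K_i2 = K_i`, and mixed leaves all
#' four dissociation constants independent.
#'
#' @param K_m,k_cat,E0,S0 as in [build_mm_qssa()].
#' @param K_i enzyme-inhibitor dissociation constant (M).
#' @param I0 total inhibitor (M).
#' @param type one of `"competitive"`, `"noncompetitive"`, `"uncompetitive"`,
#'   `"mixed"`.
#' @param K_m2 EI + S dissociation constant (M); mixed only.
#' @param K_i2 ES + I dissociation constant (M); mixed only (uncompetitive
#'   uses `K_i` for its single ESI path).
#' @return a circuit whose algebraic nodes depend on `type`.
#' @export
build_inhibition <- function(K_m, k_cat, K_i, E0, S0, I0,
                             type = c("competitive", "noncompetitive",
                                      "uncompetitive", "mixed"),
                             K_m2 = NULL, K_i2 = NULL) {
  type <- match.arg(type)
  .check_pos(K_m = K_m, k_cat = k_cat, K_i = K_i)
  .check_nonneg(E0 = E0, S0 = S0, I0 = I0)
  if (type == "noncompetitive") {
    if (!is.null(K_m2) && abs(K_m2 - K_m) > 1e-12 * K_m)
      stop("noncompetitive inhibition requires K_m2 = K_m", call. = FALSE)
    if (!is.null(K_i2) && abs(K_i2 - K_i) > 1e-12 * K_i)
      stop("noncompetitive inhibition requires K_i2 = K_i", call. = FALSE)
    K_m2 <- K_m; K_i2 <- K_i
  } else if (type == "mixed") {
    if (is.null(K_m2) || is.null(K_i2))
      stop("mixed inhibition requires K_m2 and K_i2", call. = FALSE)
    .check_pos(K_m2 = K_m2, K_i2 = K_i2)
  } else if (type == "uncompetitive") {
    if (is.null(K_i2)) K_i2 <- K_i
    .check_pos(K_i2 = K_i2)
  } else {
    if (!is.null(K_m2) || !is.null(K_i2))
      stop("competitive inhibition has no ESI branch; K_m2/K_i2 do not apply",
           call. = FALSE)
  }

  circ <- new_circuit(paste0("inhibition_", type))
  has_EI  <- type != "uncompetitive"
  has_ESI <- type != "competitive"

  circ <- add_species(circ, "ES", "algebraic", 0)
  if (has_EI)  circ <- add_species(circ, "EI", "algebraic", 0)
  if (has_ESI) circ <- add_species(circ, "ESI", "algebraic", 0)
  circ <- add_species(circ, "P", "dynamic", 0)

  e_ded <- c(ES = 1)
  if (has_EI)  e_ded <- c(e_ded, EI = 1)
  if (has_ESI) e_ded <- c(e_ded, ESI = 1)
  s_ded <- c(ES = 1, P = 1)
  if (has_ESI) s_ded <- c(s_ded, ESI = 1)
  i_ded <- c()
  if (has_EI)  i_ded <- c(i_ded, EI = 1)
  if (has_ESI) i_ded <- c(i_ded, ESI = 1)
  circ <- add_pool(circ, "E_free", total = E0, deductions = e_ded)
  circ <- add_pool(circ, "S_free", total = S0, deductions = s_ded)
  circ <- add_pool(circ, "I_free", total = I0, deductions = i_ded)

  circ <- add_transconductor(circ, "I_f1", 1, c("E_free", "S_free"),
                             "ES", "source")
  circ <- add_decay(circ, "I_dis_ES", "ES", 1 / K_m)
  if (has_EI) {
    circ <- add_transconductor(circ, "I_f3", 1, c("E_free", "I_free"),
                               "EI", "source")
    circ <- add_decay(circ, "I_dis_EI", "EI", 1 / K_i)
  }
  if (has_ESI) {
    circ <- add_transconductor(circ, "I_f2", 1, c("ES", "I_free"),
                               "ESI", "source")
    circ <- add_decay(circ, "I_dis_ESI_i", "ESI", 1 / K_i2)
    if (has_EI) {
      circ <- add_transconductor(circ, "I_f4", 1, c("EI", "S_free"),
                                 "ESI", "source")
      circ <- add_decay(circ, "I_dis_ESI_m", "ESI", 1 / K_m2)
    }
  }
  circ <- add_transconductor(circ, "I_p", k_cat, "ES", "P", "source")
  circ
}

#' Product-feedback (competitive) inhibition circuit
#'
#' Competitive inhibition where the inhibitor is the reaction's own
#' co-product (galactose for beta-galactosidase): the inhibitor pool total is
#' `Gal0 + [P]`, wiring newly produced product into the EI binding input so
#' the reaction slows itself down as it proceeds.
#'
#' @inheritParams build_inhibition
#' @param Gal0 product/inhibitor present at t = 0 (M).
#' @return a competitive-inhibition circuit with product feedback.
#' @export
build_product_feedback <- function(K_m, k_cat, K_i, E0, S0, Gal0 = 0) {
  .check_nonneg(Gal0 = Gal0)
  circ <- build_inhibition(K_m, k_cat, K_i, E0, S0, I0 = Gal0,
                           type = "competitive")
  circ$meta$name <- "product_feedback"
  # inhibitor total grows with product: I_free = Gal0 + P - EI
  circ$pools$I_free$deductions <- c(EI = 1, P = -1)
  circ
}

#' Two-substrate binding circuit (random or ordered)
#'
#' The generalized binding block with substrates A and B taking the roles of
#' substrate and inhibitor; only the ternary complex EAB feeds the catalytic
#' transconductor, and both substrate pools deduct the ternary complex and
#' the product.  Ordered variants remove the disallowed first-binding branch
#' exactly: `A_first` means E binds A before B (no EB node), `B_first` the
#' converse.
#'
#' @param KdA,KdB dissociation constants of A and B from the enzyme (M),
#'   used for both the binary and ternary dissociations (independent sites).
#' @param k_cat catalytic rate of the ternary complex (1/s).
#' @param order `"random"`, `"A_first"` or `"B_first"`.
#' @param A0,B0,E0 total concentrations (M).
#' @return a circuit with product node `P` and complexes per `order`.
#' @export
build_two_substrate <- function(KdA, KdB, k_cat,
                                order = c("random", "A_first", "B_first"),
                                A0, B0, E0) {
  order <- match.arg(order)
  .check_pos(KdA = KdA, KdB = KdB)
  .check_nonneg(k_cat = k_cat, A0 = A0, B0 = B0, E0 = E0)
  has_EA <- order != "B_first"
  has_EB <- order != "A_first"
  circ <- new_circuit(paste0("two_substrate_", order))
  if (has_EA) circ <- add_species(circ, "EA", "algebraic", 0)
  if (has_EB) circ <- add_species(circ, "EB", "algebraic", 0)
  circ <- add_species(circ, "EAB", "algebraic", 0)
  circ <- add_species(circ, "P", "dynamic", 0)

  e_ded <- c(EAB = 1)
  if (has_EA) e_ded <- c(EA = 1, e_ded)
  if (has_EB) e_ded <- c(EB = 1, e_ded)
  a_ded <- c(EAB = 1, P = 1)
  if (has_EA) a_ded <- c(EA = 1, a_ded)
  b_ded <- c(EAB = 1, P = 1)
  if (has_EB) b_ded <- c(EB = 1, b_ded)
  circ <- add_pool(circ, "E_free", total = E0, deductions = e_ded)
  circ <- add_pool(circ, "A_free", total = A0, deductions = a_ded)
  circ <- add_pool(circ, "B_free", total = B0, deductions = b_ded)

  if (has_EA) {
    circ <- add_transconductor(circ, "I_EA", 1, c("E_free", "A_free"),
                               "EA", "source")
    circ <- add_decay(circ, "I_dis_EA", "EA", 1 / KdA)
    circ <- add_transconductor(circ, "I_EAB_fromEA", 1, c("EA", "B_free"),
                               "EAB", "source")
    circ <- add_decay(circ, "I_dis_EAB_B", "EAB", 1 / KdB)
  }
  if (has_EB) {
    circ <- add_transconductor(circ, "I_EB", 1, c("E_free", "B_free"),
                               "EB", "source")
    circ <- add_decay(circ, "I_dis_EB", "EB", 1 / KdB)
    circ <- add_transconductor(circ, "I_EAB_fromEB", 1, c("EB", "A_free"),
                               "EAB", "source")
    circ <- add_decay(circ, "I_dis_EAB_A", "EAB", 1 / KdA)
  }
  # k_cat = 0 leaves a binding-only block; dynamic P then just stays at 0
  if (k_cat > 0)
    circ <- add_transconductor(circ, "I_p", k_cat, "EAB", "P", "source")
  circ
}

#' Reversible ordered Bi-Bi circuit (full mass-action)
#'
#' The five-step reversible mechanism of an NAD-dependent dehydrogenase:
#' E + NAD <-> E-NAD <-> (+S) E-NAD-S <-> E-NADH-P <-> (-P) E-NADH <-> E +
#' NADH.  Every intermediate complex keeps its capacitor (no QSSA); each
#' step contributes a forward and a reverse current, with the product
#' rebinding fluxes `k_m4 * [P][E-NADH]` and `k_m5 * [NADH][E_free]`.
#' Conservation pools: enzyme (all four complexes), the NAD moiety (all four
#' complexes plus free NADH) and the substrate moiety (S-containing
#' complexes plus P).
#'
#' @param k1,k2,k3,k4,k5 forward rate constants; k1, k2 bimolecular
#'   (1/(M s)), k3-k5 unimolecular (1/s).
#' @param k_m1,k_m2,k_m3,k_m4,k_m5 reverse rate constants; k_m4, k_m5
#'   bimolecular (1/(M s)), the rest 1/s.  Zeros remove the corresponding
#'   path (irreversible step).
#' @param E0,NAD0,S0 total enzyme, NAD+ and substrate (M).
#' @return a circuit with six dynamic nodes.
#' @export
build_reversible_bibi <- function(k1, k2, k3, k4, k5,
                                  k_m1, k_m2, k_m3, k_m4, k_m5,
                                  E0, NAD0, S0) {
  .check_nonneg(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                k_m1 = k_m1, k_m2 = k_m2, k_m3 = k_m3, k_m4 = k_m4,
                k_m5 = k_m5, E0 = E0, NAD0 = NAD0, S0 = S0)
  circ <- new_circuit("reversible_bibi")
  for (nm in c("E.NAD", "E.NAD.S", "E.NADH.P", "E.NADH", "P", "NADH"))
    circ <- add_species(circ, nm, "dynamic", 0)
  cplx <- c(E.NAD = 1, E.NAD.S = 1, E.NADH.P = 1, E.NADH = 1)
  circ <- add_pool(circ, "E_free", total = E0, deductions = cplx)
  circ <- add_pool(circ, "NAD_free", total = NAD0,
                   deductions = c(cplx, NADH = 1))
  circ <- add_pool(circ, "S_free", total = S0,
                   deductions = c(E.NAD.S = 1, E.NADH.P = 1, P = 1))

  tc <- function(circ, name, gain, inputs, target, sign)
    if (gain > 0) add_transconductor(circ, name, gain, inputs, target, sign)
    else circ
  dk <- function(circ, name, node, k)
    if (k > 0) add_decay(circ, name, node, 1 / k) else circ

  # step 1: E + NAD <-> E-NAD
  circ <- tc(circ, "step1_f", k1, c("NAD_free", "E_free"), "E.NAD", "source")
  circ <- dk(circ, "step1_r", "E.NAD", k_m1)
  # step 2: E-NAD + S <-> E-NAD-S
  circ <- tc(circ, "step2_f", k2, c("E.NAD", "S_free"), "E.NAD.S", "source")
  circ <- tc(circ, "step2_f_drain", k2, c("E.NAD", "S_free"), "E.NAD", "sink")
  circ <- dk(circ, "step2_r", "E.NAD.S", k_m2)
  circ <- tc(circ, "step2_r_return", k_m2, "E.NAD.S", "E.NAD", "source")
  # step 3: isomerization E-NAD-S <-> E-NADH-P
  circ <- dk(circ, "step3_f", "E.NAD.S", k3)
  circ <- tc(circ, "step3_f_fill", k3, "E.NAD.S", "E.NADH.P", "source")
  circ <- dk(circ, "step3_r", "E.NADH.P", k_m3)
  circ <- tc(circ, "step3_r_return", k_m3, "E.NADH.P", "E.NAD.S", "source")
  # step 4: E-NADH-P <-> E-NADH + P
  circ <- dk(circ, "step4_r", "E.NADH.P", k4)    # drains the complex
  circ <- tc(circ, "step4_f", k4, "E.NADH.P", "P", "source")
  circ <- tc(circ, "step4_f_fill", k4, "E.NADH.P", "E.NADH", "source")
  circ <- tc(circ, "step4_rebind", k_m4, c("P", "E.NADH"), "P", "sink")
  circ <- tc(circ, "step4_rebind_drain", k_m4, c("P", "E.NADH"),
             "E.NADH", "sink")
  circ <- tc(circ, "step4_rebind_fill", k_m4, c("P", "E.NADH"),
             "E.NADH.P", "source")
  # step 5: E-NADH <-> E + NADH
  circ <- dk(circ, "step5_r", "E.NADH", k5)      # drains the complex
  circ <- tc(circ, "step5_f", k5, "E.NADH", "NADH", "source")
  circ <- tc(circ, "step5_rebind", k_m5, c("NADH", "E_free"), "NADH", "sink")
  circ <- tc(circ, "step5_rebind_fill", k_m5, c("NADH", "E_free"),
             "E.NADH", "source")
  circ
}

#' Per-step net fluxes of a reversible Bi-Bi trajectory
#'
#' Forward minus reverse current for each of the five reversible steps, on
#' the trajectory's time grid.  At thermodynamic equilibrium every column
#' vanishes (detailed balance).
#'
#' @param trajectory a trajectory from a [build_reversible_bibi()] circuit.
#' @return matrix (time x 5) of net fluxes (M/s).
#' @export
bibi_step_fluxes <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  cur <- trajectory$currents
  get <- function(nm) if (nm %in% colnames(cur)) cur[, nm] else 0
  cbind(step1 = get("step1_f") - get("step1_r"),
        step2 = get("step2_f") - get("step2_r"),
        step3 = get("step3_f") - get("step3_r"),
        step4 = get("step4_f") - get("step4_rebind"),
        step5 = get("step5_f") - get("step5_rebind"))
}

#' Polymerase/ribosome sequestration multiplier
#'
#' Average number of polymerases (or ribosomes) engaged per active template
#' complex: 1 for the one bound at the promoter (or ribosome binding site)
#' plus the elongating ones, `rate * length / velocity`.
#'
#' @param rate initiation rate constant (1/s): k_TX or k_TL.
#' @param length transcript or coding length (nt).
#' @param velocity elongation velocity (nt/s).
#' @return the multiplier `1 + rate * length / velocity`, always >= 1.
#' @export
sequestration_multiplier <- function(rate, length, velocity) {
  .check_pos(rate = rate, length = length, velocity = velocity)
  1 + rate * length / velocity
}

#' Cell-free transcription-translation (TXTL) circuit with TetR repression
#'
#' The promoter DNA acts as the "enzyme" of a noncompetitive QSSA binding
#' block: RNA polymerase (the "substrate", not consumed) and the TetR
#' homodimer (the inhibitor) bind at independent sites, giving algebraic
#' complexes DNA-RNAP, DNA-TetR and DNA-RNAP-TetR.  Only free DNA-RNAP
#' drives transcription at `k_TX`; mRNA decays at `d` (applied to total
#' mRNA).  Ribosomes bind mRNA as a second QSSA block with dissociation
#' constant `K_ribo`; Ribo-mRNA drives translation of dark GFP at `k_TL`,
#' which matures into fluorescent GFP at `k_mat`.  The free polymerase pool
#' deducts `1 + k_TX*Lm/Cm` polymerases per transcribing complex (one at the
#' promoter plus the elongating ones) and one per repressed ternary complex;
#' the ribosome pool deducts `1 + k_TL*Lp/Cp` per translating mRNA.
#'
#' @param k_TX transcription initiation rate (1/s).
#' @param d mRNA degradation rate (1/s).
#' @param k_TL translation initiation rate (1/s).
#' @param k_mat GFP maturation rate (1/s).
#' @param Lm mRNA length (nt); Cm polymerase elongation velocity (nt/s).
#' @param Cm,Cp elongation velocities (nt/s).
#' @param Lp coding length (nt).
#' @param K_RNAP,K_TetR,K_ribo dissociation constants (M) of polymerase,
#'   TetR homodimer and ribosome binding.  `K_ribo` has no default: it must
#'   be supplied by the user.
#' @param DNA0,RNAP0,TetR0,Ribo0 total concentrations (M); `TetR0` counts
#'   homodimers.
#' @return a circuit with reporter nodes `GFP_dark` and `GFP`.
#' @export
build_txtl <- function(k_TX, d, k_TL, k_mat, Lm, Cm, Lp, Cp,
                       K_RNAP, K_TetR, K_ribo,
                       DNA0, RNAP0, TetR0 = 0, Ribo0) {
  .check_pos(k_TX = k_TX, d = d, k_TL = k_TL, k_mat = k_mat, Lm = Lm,
             Cm = Cm, Lp = Lp, Cp = Cp, K_RNAP = K_RNAP, K_TetR = K_TetR,
             K_ribo = K_ribo)
  .check_nonneg(DNA0 = DNA0, RNAP0 = RNAP0, TetR0 = TetR0, Ribo0 = Ribo0)
  m_rnap <- sequestration_multiplier(k_TX, Lm, Cm)
  m_ribo <- sequestration_multiplier(k_TL, Lp, Cp)

  circ <- new_circuit("txtl_tetr")
  for (nm in c("DNA.RNAP", "DNA.TetR", "DNA.RNAP.TetR", "Ribo.mRNA"))
    circ <- add_species(circ, nm, "algebraic", 0)
  for (nm in c("mRNA", "GFP_dark", "GFP"))
    circ <- add_species(circ, nm, "dynamic", 0)

  circ <- add_pool(circ, "DNA_free", total = DNA0,
                   deductions = c(DNA.RNAP = 1, DNA.TetR = 1,
                                  DNA.RNAP.TetR = 1))
  circ <- add_pool(circ, "RNAP_free", total = RNAP0,
                   deductions = c(DNA.RNAP = m_rnap, DNA.RNAP.TetR = 1))
  circ <- add_pool(circ, "TetR_free", total = TetR0,
                   deductions = c(DNA.TetR = 1, DNA.RNAP.TetR = 1))
  circ <- add_pool(circ, "mRNA_free", total = "mRNA",
                   deductions = c(Ribo.mRNA = 1))
  circ <- add_pool(circ, "Ribo_free", total = Ribo0,
                   deductions = c(Ribo.mRNA = m_ribo))

  # noncompetitive binding block: DNA ~ enzyme, RNAP ~ substrate, TetR ~ I
  circ <- add_transconductor(circ, "I_bind_RNAP", 1,
                             c("DNA_free", "RNAP_free"), "DNA.RNAP", "source")
  circ <- add_decay(circ, "I_dis_RNAP", "DNA.RNAP", 1 / K_RNAP)
  circ <- add_transconductor(circ, "I_bind_TetR", 1,
                             c("DNA_free", "TetR_free"), "DNA.TetR", "source")
  circ <- add_decay(circ, "I_dis_TetR", "DNA.TetR", 1 / K_TetR)
  circ <- add_transconductor(circ, "I_bind_tern_i", 1,
                             c("DNA.RNAP", "TetR_free"),
                             "DNA.RNAP.TetR", "source")
  circ <- add_transconductor(circ, "I_bind_tern_s", 1,
                             c("DNA.TetR", "RNAP_free"),
                             "DNA.RNAP.TetR", "source")
  circ <- add_decay(circ, "I_dis_tern_i", "DNA.RNAP.TetR", 1 / K_TetR)
  circ <- add_decay(circ, "I_dis_tern_s", "DNA.RNAP.TetR", 1 / K_RNAP)

  # transcription, mRNA turnover, ribosome binding, translation, maturation
  circ <- add_transconductor(circ, "I_TX", k_TX, "DNA.RNAP", "mRNA", "source")
  circ <- add_decay(circ, "I_deg_mRNA", "mRNA", 1 / d)
  circ <- add_transconductor(circ, "I_bind_ribo", 1,
                             c("Ribo_free", "mRNA_free"),
                             "Ribo.mRNA", "source")
  circ <- add_decay(circ, "I_dis_ribo", "Ribo.mRNA", 1 / K_ribo)
  circ <- add_transconductor(circ, "I_TL", k_TL, "Ribo.mRNA",
                             "GFP_dark", "source")
  circ <- add_decay(circ, "I_mat", "GFP_dark", 1 / k_mat)
  circ <- add_transconductor(circ, "I_GFP", k_mat, "GFP_dark", "GFP",
                             "source")
  circ
}
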