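test_that("production-decay motif covers steady state, pure decay and linear growth", {
  # steady state V_in * k_cat * r = 2
  tr <- simulate_circuit(build_production_decay(1, 2, 1), 30,
                         fast_settings())
  expect_equal(unname(tr$values[nrow(tr$values), "P"]), 2, tolerance = 1e-4)

  # pure decay from P0
  trd <- simulate_circuit(build_production_decay(1, 2, V_in = 0, P0 = 1),
                          10, fast_settings())
  expect_equal(unname(trd$values[, "P"]), exp(-trd$times / 2),
               tolerance = 1e-6)

  # no decay path: linear growth at V_in * k_cat
  trl <- simulate_circuit(build_production_decay(3, Inf, 2), 10,
                          fast_settings())
  expect_equal(unname(trl$values[, "P"]), 6 * trl$times, tolerance = 1e-8)

  expect_error(build_production_decay(-1, 2, 1), "> 0")
})

test_that("exact mass-action MM behaves at its boundary cases", {
  # no enzyme: nothing happens
  tr0 <- simulate_circuit(build_mm_exact(1e6, 40, 10, E0 = 0, S0 = 1e-3),
                          100, fast_settings(50))
  expect_equal(max(abs(tr0$values[, "P"])), 0)

  # initial ES flux is k_f * S0 * E0
  circ <- build_mm_exact(1e6, 40, 10, 1e-6, 2e-3)
  expect_equal(net_current(circ, "ES", c(ES = 0, P = 0)),
               1e6 * 2e-3 * 1e-6)

  expect_error(build_mm_exact(k_cat = 10, E0 = 1e-6, S0 = 1e-3),
               "build_mm_qssa")
  expect_error(build_mm_exact(1e6, 40, 10, 1e-6, 1e-3, K_m = 1),
               "inconsistent")
})

test_that("exact MM converges to the QSSA circuit as k_f grows at fixed K_m", {
  K_m <- 1e-4; k_cat <- 10; E0 <- 1e-8; S0 <- 1e-3
  qssa <- simulate_circuit(build_mm_qssa(K_m, k_cat, E0, S0), 2000,
                           fast_settings(150))
  dev <- vapply(c(1e6, 1e7, 1e8, 1e9), function(k_f) {
    k_r <- K_m * k_f - k_cat
    ex <- simulate_circuit(build_mm_exact(k_f, k_r, k_cat, E0, S0), 2000,
                           fast_settings(150))
    max(abs(ex$values[, "P"] - qssa$values[, "P"]))
  }, 0)
  expect_true(all(diff(dev) < 0))              # monotone over 3 decades
  expect_lt(dev[2] / S0, 0.01)                 # within 1% already at 1e7
})

test_that("QSSA motif maps K_m to the dissociation resistor", {
  circ <- build_mm_qssa(betagal$K_m, betagal$k_cat, betagal$E0, betagal$S0)
  expect_equal(round(decay_resistances(circ)[["I_dis"]]), 5988)
  expect_error(build_mm_qssa(-1e-4, 10, 1e-8, 1e-3), "> 0")
})

test_that("inhibition circuits reduce and specialize correctly", {
  # no inhibitor: identical product trajectory to the plain MM motif
  mm <- simulate_circuit(build_mm_qssa(2e-3, 500, 1e-8, 5e-3), 800,
                         fast_settings(100))
  comp0 <- simulate_circuit(
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, I0 = 0, "competitive"),
    800, fast_settings(100))
  expect_equal(unname(comp0$values[, "P"]), unname(mm$values[, "P"]),
               tolerance = 1e-9)

  # mixed with K_m2 = K_m, K_i2 = K_i equals an independently built
  # noncompetitive circuit
  non <- simulate_circuit(
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3, "noncompetitive"),
    800, fast_settings(100))
  mix <- simulate_circuit(
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3, "mixed",
                     K_m2 = 2e-3, K_i2 = 3e-3),
    800, fast_settings(100))
  expect_equal(unname(mix$values[, "P"]), unname(non$values[, "P"]),
               tolerance = 1e-9)

  expect_error(build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3,
                                "noncompetitive", K_m2 = 4e-3),
               "K_m2 = K_m")
  expect_error(build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3,
                                "mixed"), "K_m2 and K_i2")
  expect_error(build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3,
                                "competitive", K_i2 = 1e-3), "no ESI")
})

test_that("competitive inhibition shifts apparent K_m by 1 + I/K_i", {
  # PETG on beta-galactosidase: K_i = 2.33 uM, I0 = 10 uM
  K_i <- 2.33e-6; I0 <- 1e-5
  grid <- betagal$K_m * c(0.3, 0.5, 0.8, 1.2, 2, 3.5, 6, 10, 18, 30)
  fit <- lineweaver_burk(rate_curve(
    function(s0) build_inhibition(betagal$K_m, betagal$k_cat, K_i,
                                  betagal$E0, s0, I0, "competitive"),
    grid, t_end = 20, consumption_cap = 0.01, E0 = betagal$E0))
  expect_equal(fit$K_m_app, betagal$K_m * (1 + I0 / K_i), tolerance = 0.01)
  expect_equal(fit$V_max_app, betagal$k_cat * betagal$E0, tolerance = 0.01)
})

test_that("product feedback slows the reaction without changing the end point", {
  pars <- list(K_m = 1.67e-4, k_cat = 2903, K_i = 1.37e-2, E0 = 7e-10,
               S0 = 1e-3)
  base <- simulate_circuit(
    do.call(build_product_feedback, c(pars, Gal0 = 0)), 6000,
    fast_settings(150))
  fed <- simulate_circuit(
    do.call(build_product_feedback, c(pars, Gal0 = 4e-2)), 6000,
    fast_settings(150))
  # inhibited run is slower at every interior time point...
  mid <- 2:(150 - 1)
  expect_true(all(fed$values[mid, "P"] < base$values[mid, "P"]))
  # ...but inhibition does not consume substrate: same plateau
  expect_equal(unname(fed$values[150, "P"]), pars$S0, tolerance = 1e-3)

  # with K_i effectively infinite and no added product, plain MM returns
  mm <- simulate_circuit(build_mm_qssa(pars$K_m, pars$k_cat, pars$E0,
                                       pars$S0), 6000, fast_settings(150))
  off <- simulate_circuit(
    build_product_feedback(pars$K_m, pars$k_cat, K_i = 1e6, pars$E0,
                           pars$S0, Gal0 = 0), 6000, fast_settings(150))
  expect_equal(unname(off$values[, "P"]), unname(mm$values[, "P"]),
               tolerance = 1e-6)
})

test_that("two-substrate binding order matters as S/Kd predicts", {
  # symmetric substrates: both orders coincide
  a <- simulate_circuit(build_two_substrate(2e-3, 2e-3, 500, "A_first",
                                            2e-3, 2e-3, 1e-8),
                        500, fast_settings(100))
  b <- simulate_circuit(build_two_substrate(2e-3, 2e-3, 500, "B_first",
                                            2e-3, 2e-3, 1e-8),
                        500, fast_settings(100))
  expect_equal(unname(a$values[, "P"]), unname(b$values[, "P"]),
               tolerance = 1e-9)

  # B has the smaller S/Kd (same S, larger Kd): binding B first is faster
  fastr <- simulate_circuit(build_two_substrate(2e-3, 8e-3, 500, "B_first",
                                                2e-3, 2e-3, 1e-8),
                            500, fast_settings(100))
  slowr <- simulate_circuit(build_two_substrate(2e-3, 8e-3, 500, "A_first",
                                                2e-3, 2e-3, 1e-8),
                            500, fast_settings(100))
  mid <- 5:95
  expect_true(all(fastr$values[mid, "P"] >= slowr$values[mid, "P"]))
  expect_gt(max(fastr$values[, "P"] - slowr$values[, "P"]), 0)

  # k_cat = 0: the binding block equilibrates but makes no product
  eq <- simulate_circuit(build_two_substrate(2e-3, 4e-3, 0, "random",
                                             2e-3, 2e-3, 1e-8),
                         100, fast_settings(50))
  expect_equal(max(abs(eq$values[, "P"])), 0)
  expect_gt(min(eq$values[, "EAB"]), 0)
  expect_error(build_two_substrate(2e-3, 4e-3, 500, "sideways",
                                   2e-3, 2e-3, 1e-8))
})

test_that("time to half-completion favors binding the smaller-S/Kd substrate first", {
  half_time <- function(tr) {
    p <- tr$values[, "P"]
    target <- 0.5 * max(p)
    tr$times[which(p >= target)[1]]
  }
  for (kdb_scale in c(2, 4, 8)) {
    hb <- half_time(simulate_circuit(
      build_two_substrate(2e-3, 2e-3 * kdb_scale, 500, "B_first",
                          2e-3, 2e-3, 1e-8), 800, fast_settings(200)))
    ha <- half_time(simulate_circuit(
      build_two_substrate(2e-3, 2e-3 * kdb_scale, 500, "A_first",
                          2e-3, 2e-3, 1e-8), 800, fast_settings(200)))
    expect_lte(hb, ha)   # B has smaller S/Kd here
  }
})

test_that("reversible Bi-Bi conserves pools and reaches detailed balance", {
  rates <- list(k1 = 1e6, k2 = 5e5, k3 = 100, k4 = 80, k5 = 50,
                k_m1 = 50, k_m2 = 40, k_m3 = 60, k_m4 = 1e5, k_m5 = 2e5)
  circ <- do.call(build_reversible_bibi,
                  c(rates, E0 = 1e-6, NAD0 = 4e-3, S0 = 1e-2))
  tr <- simulate_circuit(circ, 5000, fast_settings(200))

  # NAD moiety identity at every time point, assembled independently
  nad_sum <- tr$free[, "NAD_free"] +
    rowSums(tr$values[, c("E.NAD", "E.NAD.S", "E.NADH.P", "E.NADH",
                          "NADH")])
  expect_equal(unname(nad_sum), rep(4e-3, length(tr$times)),
               tolerance = 1e-10)

  # equilibrium: every step's net flux vanishes
  nf <- bibi_step_fluxes(tr)
  expect_lt(max(abs(nf[nrow(nf), ])), 1e-5 * max(abs(nf)))

  # irreversible limit: full conversion to min(S0, NAD0)
  circ_ir <- build_reversible_bibi(1e6, 5e5, 100, 80, 50, 0, 0, 0, 0, 0,
                                   E0 = 1e-6, NAD0 = 2e-3, S0 = 1e-2)
  tr_ir <- simulate_circuit(circ_ir, 20000, fast_settings(150))
  expect_equal(unname(tr_ir$values[150, "P"]), 2e-3, tolerance = 1e-3)
  expect_error(build_reversible_bibi(1e6, 5e5, 100, 80, 50, 0, 0, 0, 0,
                                     E0 = 1e-6, NAD0 = 2e-3, S0 = 1e-2))
})

test_that("TXTL motif wires sequestration, repression and maturation", {
  expect_equal(sequestration_multiplier(0.05, 1000, 50), 2)

  pars <- list(k_TX = 0.05, d = 0.002, k_TL = 0.05, k_mat = 0.002,
               Lm = 1000, Cm = 50, Lp = 720, Cp = 30,
               K_RNAP = 1e-7, K_TetR = 1e-9, K_ribo = 5e-8,
               DNA0 = 6e-9, RNAP0 = 1e-7, Ribo0 = 3e-7)
  tr0 <- simulate_circuit(do.call(build_txtl, c(pars, TetR0 = 0)),
                          4000, fast_settings(150))
  # no repressor: both TetR complexes stay empty
  expect_equal(max(abs(tr0$values[, "DNA.TetR"])), 0)
  expect_equal(max(abs(tr0$values[, "DNA.RNAP.TetR"])), 0)

  # hand-assembled uninhibited TXTL (no TetR branch at all) as oracle
  m_rnap <- sequestration_multiplier(pars$k_TX, pars$Lm, pars$Cm)
  m_ribo <- sequestration_multiplier(pars$k_TL, pars$Lp, pars$Cp)
  h <- new_circuit("txtl_plain")
  for (nm in c("DNA.RNAP", "Ribo.mRNA")) h <- add_species(h, nm, "algebraic")
  for (nm in c("mRNA", "GFP_dark", "GFP")) h <- add_species(h, nm, "dynamic")
  h <- add_pool(h, "DNA_free", pars$DNA0, c(DNA.RNAP = 1))
  h <- add_pool(h, "RNAP_free", pars$RNAP0,
                stats::setNames(m_rnap, "DNA.RNAP"))
  h <- add_pool(h, "mRNA_free", "mRNA", c(Ribo.mRNA = 1))
  h <- add_pool(h, "Ribo_free", pars$Ribo0,
                stats::setNames(m_ribo, "Ribo.mRNA"))
  h <- add_transconductor(h, "b1", 1, c("DNA_free", "RNAP_free"),
                          "DNA.RNAP", "source")
  h <- add_decay(h, "d1", "DNA.RNAP", 1 / pars$K_RNAP)
  h <- add_transconductor(h, "tx", pars$k_TX, "DNA.RNAP", "mRNA", "source")
  h <- add_decay(h, "deg", "mRNA", 1 / pars$d)
  h <- add_transconductor(h, "b2", 1, c("Ribo_free", "mRNA_free"),
                          "Ribo.mRNA", "source")
  h <- add_decay(h, "d2", "Ribo.mRNA", 1 / pars$K_ribo)
  h <- add_transconductor(h, "tl", pars$k_TL, "Ribo.mRNA", "GFP_dark",
                          "source")
  h <- add_decay(h, "mat", "GFP_dark", 1 / pars$k_mat)
  h <- add_transconductor(h, "gfp", pars$k_mat, "GFP_dark", "GFP", "source")
  tr_h <- simulate_circuit(h, 4000, fast_settings(150))
  expect_equal(unname(tr0$values[, "GFP"]), unname(tr_h$values[, "GFP"]),
               tolerance = 1e-8)

  # monotone repression of the steady GFP production rate
  late_rate <- function(tetr0) {
    tr <- simulate_circuit(do.call(build_txtl, c(pars, TetR0 = tetr0)),
                           4000, fast_settings(150))
    idx <- tr$times >= 3000
    .lm <- stats::lm(tr$values[idx, "GFP"] ~ tr$times[idx])
    unname(stats::coef(.lm)[2])
  }
  rates_by_tetr <- vapply(c(0, 2e-9, 10e-9, 50e-9), late_rate, 0)
  expect_true(all(diff(rates_by_tetr) < 0))
  expect_error(do.call(build_txtl, c(pars[-1], TetR0 = 0)))
})

test_that("every motif circuit validates cleanly", {
  circs <- list(
    build_production_decay(1, 2, 1),
    build_mm_exact(1e6, 40, 10, 1e-6, 2e-3),
    build_mm_qssa(2e-3, 500, 1e-8, 5e-3),
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3, "competitive"),
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3, "uncompetitive"),
    build_inhibition(2e-3, 500, 3e-3, 1e-8, 5e-3, 3e-3, "mixed",
                     K_m2 = 4e-3, K_i2 = 6e-3),
    build_product_feedback(1.67e-4, 2903, 1.37e-2, 7e-10, 1e-3, 4e-2),
    build_two_substrate(2e-3, 4e-3, 500, "random", 2e-3, 2e-3, 1e-8),
    build_reversible_bibi(1e6, 5e5, 100, 80, 50, 50, 40, 60, 1e5, 2e5,
                          1e-6, 4e-3, 1e-2),
    build_txtl(0.05, 0.002, 0.05, 0.002, 1000, 50, 720, 30,
               1e-7, 1e-9, 5e-8, 6e-9, 1e-7, 1e-8, 3e-7)
  )
  for (circ in circs) expect_length(validate_circuit(circ), 0)
})
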