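test_that("initial_rate recovers slopes exactly and guards its window", {
  # fabricate a linear-ramp trajectory via a no-decay production node
  tr <- simulate_circuit(build_production_decay(3, Inf, 2), 10,
                         fast_settings(50))
  expect_equal(initial_rate(tr, "P"), 6, tolerance = 1e-10)

  flat <- simulate_circuit(build_production_decay(1, 2, V_in = 0), 10,
                           fast_settings(50))
  expect_equal(initial_rate(flat, "P"), 0)

  expect_error(initial_rate(tr, "P", c(0, 0.1)), "at least 5")
  expect_error(initial_rate(tr, "P", c(0, 99)), "outside")
  expect_error(initial_rate(tr, "Q"), "unknown product")

  # beta-gal assay: first-minute slope vs the free-ligand closed form
  circ <- build_mm_qssa(betagal$K_m, betagal$k_cat, betagal$E0, betagal$S0)
  trb <- simulate_circuit(circ, 60, fast_settings(100))
  expect_equal(initial_rate(trb, "P"),
               mm_rate(betagal$S0, betagal$K_m, betagal$k_cat * betagal$E0),
               tolerance = 0.02)
})

test_that("rate curves are hyperbolic: zero, midpoint and plateau behavior", {
  K_m <- 2e-3; k_cat <- 500; E0 <- 1e-8
  V_max <- k_cat * E0
  ra <- rate_curve(function(s0) build_mm_qssa(K_m, k_cat, E0, s0),
                   c(0, K_m, 100 * K_m), t_end = 10,
                   consumption_cap = 0.01, E0 = E0)
  expect_equal(ra$V0[1], 0)
  expect_equal(ra$V0[2], V_max / 2, tolerance = 0.02)   # S0 = K_m midpoint
  expect_equal(ra$V0[3], V_max, tolerance = 0.02)       # saturating plateau
  # monotone non-decreasing in S0
  expect_true(all(diff(ra$V0) >= 0))
})

test_that("Lineweaver-Burk inverts noiseless MM rates essentially exactly", {
  K_m <- 2e-3; V_max <- 5e-6
  S0 <- c(0.5, 1, 2, 4, 8, 16) * 1e-3
  fit <- lineweaver_burk(S0, mm_rate(S0, K_m, V_max))
  expect_equal(fit$K_m_app, K_m, tolerance = 1e-6)
  expect_equal(fit$V_max_app, V_max, tolerance = 1e-6)
  # intercept conventions: Y-intercept = 1/V_max, X-intercept = -1/K_m
  expect_equal(fit$y_intercept, 1 / V_max, tolerance = 1e-6)
  expect_equal(fit$x_intercept, -1 / K_m, tolerance = 1e-6)
  expect_equal(fit$K_m_app, -1 / fit$x_intercept, tolerance = 1e-12)

  expect_error(lineweaver_burk(c(1e-3, 2e-3), c(1e-6, 2e-6)), "at least 3")
})

test_that("round-trip recovery holds for all four inhibition mechanisms", {
  V_max <- inhib$k_cat * inhib$E0
  grid <- c(0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 20) * 1e-3
  cases <- list(
    list(type = "competitive",    K_i2 = NULL),
    list(type = "uncompetitive",  K_i2 = NULL),
    list(type = "mixed",          K_i2 = 6e-3, K_m2 = 4e-3)
  )
  for (cs in cases) {
    fit <- lineweaver_burk(rate_curve(
      function(s0) build_inhibition(inhib$K_m, inhib$k_cat, inhib$K_i,
                                    inhib$E0, s0, inhib$I0, cs$type,
                                    K_m2 = cs$K_m2, K_i2 = cs$K_i2),
      grid, t_end = 10, consumption_cap = 0.01, E0 = inhib$E0))
    exp_par <- apparent_params(cs$type, inhib$K_m, V_max, inhib$I0,
                               inhib$K_i,
                               K_i2 = if (is.null(cs$K_i2)) inhib$K_i
                                      else cs$K_i2)
    expect_equal(fit$K_m_app, exp_par$K_m, tolerance = 0.01,
                 label = paste(cs$type, "K_m_app"))
    expect_equal(fit$V_max_app, exp_par$V_max, tolerance = 0.01,
                 label = paste(cs$type, "V_max_app"))
  }
})

test_that("inhibition classification reads the fit changes correctly", {
  V_max <- inhib$k_cat * inhib$E0
  grid <- c(0.5, 1, 2, 4, 8, 16) * 1e-3
  base_fit <- lineweaver_burk(rate_curve(
    function(s0) build_mm_qssa(inhib$K_m, inhib$k_cat, inhib$E0, s0),
    grid, t_end = 10, consumption_cap = 0.01, E0 = inhib$E0))

  fit_for <- function(type, ...) lineweaver_burk(rate_curve(
    function(s0) build_inhibition(inhib$K_m, inhib$k_cat, inhib$K_i,
                                  inhib$E0, s0, inhib$I0, type, ...),
    grid, t_end = 10, consumption_cap = 0.01, E0 = inhib$E0))

  expect_identical(classify_inhibition(base_fit, base_fit)$type, "none")
  expect_identical(classify_inhibition(base_fit,
                                       fit_for("competitive"))$type,
                   "competitive")
  expect_identical(classify_inhibition(base_fit,
                                       fit_for("noncompetitive"))$type,
                   "noncompetitive")
  expect_identical(classify_inhibition(base_fit,
                                       fit_for("uncompetitive"))$type,
                   "uncompetitive")
  expect_identical(classify_inhibition(
    base_fit, fit_for("mixed", K_m2 = 4e-3, K_i2 = 6e-3))$type, "mixed")

  other <- base_fit; other$E0 <- 2 * inhib$E0
  expect_error(classify_inhibition(base_fit, other), "incomparable")
})

test_that("noisy fixtures still recover K_m within 15% (seeded Monte-Carlo)", {
  grid <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5) * 1e-3
  study <- km_recovery_study(betagal$K_m, betagal$k_cat, betagal$E0,
                             grid, t_end = 20, n_seeds = 10,
                             noise_sd_fraction = 0.05, seed = 42)
  expect_gte(study$fraction_within, 0.9)
  # determinism of the study itself
  study2 <- km_recovery_study(betagal$K_m, betagal$k_cat, betagal$E0,
                              grid, t_end = 20, n_seeds = 10,
                              noise_sd_fraction = 0.05, seed = 42)
  expect_identical(study$K_m_hat, study2$K_m_hat)
})
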