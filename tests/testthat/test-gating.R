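# Gating model: Hill fractions, effective rates, analytic propagator,
# steady states, time constants and the detailed-balance constraint.

test_that("Hill fraction handles midpoints, limits and extreme cooperativity", {
  expect_identical(hillFraction(110, 110, 24), 0.5)
  expect_identical(hillFraction(0, 196, 24), 0)
  # frozen high-precision value of 170^24/(170^24 + 196^24)
  expect_equal(hillFraction(170, 196, 24), 0.03181179591598442,
               tolerance = 1e-12)
  # log-space evaluation survives n = 24 across the full working range
  ca <- c(1e-3, 1, 50, 500, 1e5, 1e7)
  f <- hillFraction(ca, 196, 24)
  expect_true(all(is.finite(f) & f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_equal(hillFraction(1e7, 196, 24), 1, tolerance = 1e-12)
  expect_error(hillFraction(-1, 196, 24), "ca")
  expect_error(hillFraction(100, 0, 24), "K")
  expect_error(hillFraction(100, 196, 0.5), "n")
})

test_that("effective rates collapse to the expected conformational rates", {
  # at 50 nM both binding fractions are ~0: out -> k_R_I2, in -> k_I2_R
  k <- transitionRates(50, heart)
  expect_equal(k$out, 3.98e-6, tolerance = 1e-4)
  expect_equal(k$into, 0.0384, tolerance = 1e-6)
  # saturating: out -> k_O_I1, in -> k_I1_O
  ks <- transitionRates(1e7, heart)
  expect_equal(ks$out, 100, tolerance = 1e-12)
  expect_equal(ks$into, 0.0364, tolerance = 1e-12)
  # equal pair makes the exit rate ca-independent
  p <- ramParams(X_RaM = 1, K_Ca = 340, n = 24, K_O = 224, K_I = 110,
                 k_O_I1 = 2, k_I1_O = 1, k_I2_R = 1, k_R_I2 = 2)
  outs <- vapply(c(10, 100, 224, 1000), function(ca)
    transitionRates(ca, p)$out, numeric(1))
  expect_equal(max(outs) - min(outs), 0, tolerance = 1e-14)
})

test_that("dRO/dt matches hand evaluation and vanishes at steady state", {
  expect_equal(dROdt(1, 0, heart), -heart$k_R_I2)
  expect_equal(dROdt(0.5, 50, heart), 0.0192, tolerance = 1e-3)
  for (ca in c(0, 50, 150, 224, 500)) {
    expect_equal(dROdt(steadyStateRO(ca, heart), ca, heart), 0,
                 tolerance = 1e-15)
  }
  expect_error(dROdt(1.2, 50, heart), "RO")
})

test_that("steady-state RO has the correct limits and monotonicity", {
  expect_equal(steadyStateRO(1e-6, heart), 0.0384 / (0.0384 + 3.98e-6),
               tolerance = 1e-9)
  expect_equal(steadyStateRO(1e7, heart), 0.0364 / 100.0364,
               tolerance = 1e-9)
  ca <- c(0, 10, 50, 90, 110, 130, 160, 196, 224, 300, 500, 1e3, 1e5)
  for (p in list(heart, liver)) {
    ss <- steadyStateRO(ca, p)
    expect_true(all(diff(ss) <= 1e-14))
  }
  p_sym <- ramParams(X_RaM = 1, K_Ca = 340, n = 24, K_O = 224, K_I = 110,
                     k_O_I1 = 3, k_I1_O = 3, k_I2_R = 3, k_R_I2 = 3)
  expect_equal(steadyStateRO(c(1, 100, 1e4), p_sym), rep(0.5, 3))
})

test_that("time constants reproduce the slow/fast tissue contrast and limits", {
  expect_equal(timeConstant(50, heart), 26.03897, tolerance = 1e-6)
  expect_equal(timeConstant(1e7, heart), 1 / 100.0364, tolerance = 1e-9)
  expect_equal(timeConstant(50, liver), 1 / 101, tolerance = 1e-4)
  # closed-form limits of the convex-combination rates
  for (p in list(heart, liver)) {
    expect_equal(timeConstant(1e-8, p), 1 / (p$k_R_I2 + p$k_I2_R),
                 tolerance = 1e-10)
    expect_equal(timeConstant(1e8, p), 1 / (p$k_O_I1 + p$k_I1_O),
                 tolerance = 1e-10)
  }
})

test_that("analytic RO course: initial condition, asymptote, e-folding", {
  for (p in list(heart, liver)) for (ca in c(50, 170, 300)) {
    ro_inf <- steadyStateRO(ca, p)
    tau <- timeConstant(ca, p)
    expect_identical(roAnalytic(0, 0.7, ca, p), 0.7)
    expect_equal(roAnalytic(1e9, 0.7, ca, p), ro_inf, tolerance = 1e-12)
    expect_equal(roAnalytic(tau, 0.7, ca, p),
                 ro_inf + (0.7 - ro_inf) * exp(-1), tolerance = 1e-12)
  }
  expect_error(roAnalytic(-1, 0.5, 50, heart), "t")
})

test_that("analytic solution agrees with adaptive numerical integration", {
  t_out <- c(0, 10^seq(-2, log10(300), length.out = 25))
  for (p in list(heart, liver)) for (ca in c(50, 150, 500)) {
    for (ro0 in c(0, 1)) {
      num <- integrateRO(t_out, ro0, ca, p)
      ana <- roAnalytic(t_out, ro0, ca, p)
      expect_lt(max(abs(num - ana)), 1e-8)
    }
  }
})

test_that("state fractions conserve probability and stay in bounds", {
  set.seed(11)
  for (i in 1:50) {
    ro <- runif(1)
    ca <- 10^runif(1, 0, 4)
    p <- if (i %% 2) heart else liver
    fr <- stateFractions(ro, ca, p)
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    # super-state conservation
    expect_equal(fr$R + fr$O, ro, tolerance = 1e-14)
    expect_equal(fr$I1 + fr$I2, 1 - ro, tolerance = 1e-14)
  }
})

test_that("printed parameter sets close the thermodynamic cycle within rounding", {
  expect_lt(abs(log(balanceResidual(heart))), 0.1)
  expect_lt(abs(log(balanceResidual(liver))), 0.1)
  expect_error(
    ramParams(X_RaM = 1, K_Ca = 340, n = 24, K_O = 224, K_I = 110,
              k_O_I1 = 100, k_I1_O = 1, k_I2_R = 1, k_R_I2 = 1,
              balanced = TRUE),
    "balanced")
})

test_that("detailed-balance enforcement closes the cycle exactly", {
  for (p in list(heart, liver)) {
    for (dep in c("k_I1_O", "k_R_I2", "k_O_I1", "k_I2_R")) {
      b <- enforceDetailedBalance(p, dep)
      expect_lt(abs(log(balanceResidual(b))), 1e-12)
      # every non-dependent field untouched
      for (f in setdiff(names(p), c(dep, "balanced")))
        expect_identical(b[[f]], p[[f]])
    }
    # a point already on the constraint surface is a fixed point for any
    # choice of dependent rate: one shared constraint surface
    b1 <- enforceDetailedBalance(p, "k_I1_O")
    b2 <- enforceDetailedBalance(b1, "k_R_I2")
    expect_equal(b2$k_R_I2, b1$k_R_I2, tolerance = 1e-12)
  }
})

test_that("balance-implied rates reproduce the published derived values", {
  # liver I1->O: printed 0.009
  expect_equal(enforceDetailedBalance(liver, "k_I1_O")$k_I1_O,
               0.009534078671663056, tolerance = 1e-12)
  # heart I1->O: printed 0.0364
  expect_equal(enforceDetailedBalance(heart, "k_I1_O")$k_I1_O,
               0.03731815430172841, tolerance = 1e-12)
  # heart with liver's I1->O rate: R->I2 must rise to 1.65e-5/s
  p <- heart
  p$k_I1_O <- 0.009
  expect_equal(enforceDetailedBalance(p, "k_R_I2")$k_R_I2, 1.65e-5,
               tolerance = 5e-4)
})

test_that("recovery time follows the closed form tau * log(20)", {
  expect_equal(recoveryTime(heart, 50),
               timeConstant(50, heart) * log(0.9998963649 / (0.9998963649 * 0.05)),
               tolerance = 1e-6)
  expect_equal(recoveryTime(liver, 50), 0.02966072, tolerance = 1e-6)
  # already above the target: no waiting
  expect_identical(recoveryTime(heart, 50, RO0 = 0.999, frac = 0.5), 0)
})
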