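# Weighted least-squares objective, synthetic data generator, sensitivity
# matrix, Fisher-information intervals and parameter recovery.

make_heart_dataset <- function(noise_cv, seed, replicates = 1L) {
  synthesizeDataset(heart_bal, referenceProtocols("heart", replicates),
                    noise_cv, seed = seed, env = env0)
}

test_that("objective: perfect fit, unit residual, variance linearity", {
  protos <- list(pulseProtocol(pulse_height = 209, pulse_duration = 5))
  y <- simulateProtocol(protos[[1]], heart_bal, env0)$total_pulse_uptake
  ds_perfect <- experimentDataset(protos, y, 1e-4, "heart")
  expect_equal(wlsObjective(heart_bal, ds_perfect, env0), 0)
  # a residual of one standard deviation contributes exactly 1
  sigma <- 0.02
  ds_unit <- experimentDataset(protos, y + sigma, sigma^2, "heart")
  expect_equal(wlsObjective(heart_bal, ds_unit, env0), 1, tolerance = 1e-10)
  # doubling every variance halves the objective
  ds <- make_heart_dataset(0.05, seed = 3)
  ds2 <- ds; ds2$variance <- 2 * ds$variance
  expect_equal(wlsObjective(heart_bal, ds2, env0),
               wlsObjective(heart_bal, ds, env0) / 2, tolerance = 1e-12)
})

test_that("synthetic generator: determinism, zero-noise exactness, empirical CV", {
  protos <- referenceProtocols("heart", 1)
  d1 <- synthesizeDataset(heart_bal, protos, 0.05, seed = 9, env = env0)
  d2 <- synthesizeDataset(heart_bal, protos, 0.05, seed = 9, env = env0)
  expect_identical(d1$observed, d2$observed)
  d3 <- synthesizeDataset(heart_bal, protos, 0.05, seed = 10, env = env0)
  expect_false(identical(d1$observed, d3$observed))
  d0 <- synthesizeDataset(heart_bal, protos, 0, seed = 9, env = env0)
  y <- vapply(protos, ramkin:::protocolPulseUptake, numeric(1),
              p = heart_bal, env = env0)
  expect_identical(d0$observed, y)
  expect_true(all(d0$variance > 0))
  # empirical CV over 1000 replicate draws of one record
  one <- list(pulseProtocol(pulse_height = 209, pulse_duration = 5))
  obs <- vapply(1:1000, function(s)
    synthesizeDataset(heart_bal, one, 0.05, seed = s, env = env0)$observed,
    numeric(1))
  expect_equal(stats::sd(obs) / mean(obs), 0.05, tolerance = 0.1)
})

test_that("sensitivity matrix: zero columns, analytic column, sigma scaling", {
  ds <- make_heart_dataset(0.05, seed = 4)
  spec <- fitSpec(free = c("X_RaM", "K_Ca", "K_O"))
  S <- sensitivityMatrix(heart_bal, ds, spec, env0)
  # uptake is exactly proportional to X_RaM, so the normalized derivative
  # equals the normalized output itself: an analytic oracle for column 1
  sigma <- sqrt(ds$variance)
  y <- vapply(ds$protocols, ramkin:::protocolPulseUptake, numeric(1),
              p = heart_bal, env = env0)
  expect_equal(S[, "X_RaM"], y / sigma, tolerance = 1e-6)
  # a parameter the output (effectively) does not depend on gives a zero
  # column: a 1 ms single pulse launched from RO = 1 at 300 nM never
  # exercises the slow recovery pathway, so k_I2_R (with the balance
  # constraint eliminating k_R_I2, not k_I1_O) is inert
  spec_inert <- fitSpec(free = c("X_RaM", "k_I2_R"),
                        dependent_rate = "k_R_I2")
  ds_single <- experimentDataset(
    list(pulseProtocol(pulse_height = 300, pulse_duration = 0.001,
                       prepulse_equilibration = FALSE)),
    0.1, 1e-4, "heart")
  S2 <- sensitivityMatrix(heart_bal, ds_single, spec_inert, env0)
  expect_lt(abs(S2[, "k_I2_R"]), 1e-6 * abs(S2[, "X_RaM"]))
  # scaling all sigma by c scales S by 1/c
  ds_c <- ds; ds_c$variance <- 4 * ds$variance
  S_c <- sensitivityMatrix(heart_bal, ds_c, spec, env0)
  expect_equal(S_c, S / 2, tolerance = 1e-10)
})

test_that("finite differences reproduce an analytic derivative to O(step^2)", {
  # single-segment closed form differentiated by hand with respect to K_Ca:
  # d y / d K_Ca = -y * ca^-1 ... via the Michaelis factor ca/(ca + K_Ca)
  pr <- pulseProtocol(pulse_height = 300, pulse_duration = 5)
  ds <- experimentDataset(list(pr), 0.5, 1e-4, "heart")
  spec <- fitSpec(free = c("K_Ca"), fd_relative_step = 1e-6)
  S <- sensitivityMatrix(heart_bal, ds, spec, env0)
  y <- ramkin:::protocolPulseUptake(pr, heart_bal, env0)
  dy_dKCa <- -y / (300 + heart_bal$K_Ca)
  expect_equal(as.numeric(S[1, "K_Ca"]),
               heart_bal$K_Ca * dy_dKCa / sqrt(1e-4), tolerance = 1e-8)
})

test_that("covariance and intervals: diagonal case, footnote rule, pseudo-inverse", {
  S <- diag(c(4, 0.5))
  colnames(S) <- c("a", "b")
  p <- c(a = 2, b = 10)
  cc <- covarianceCI(S, p)
  expect_equal(diag(cc$C), c(a = 1 / 16, b = 4), tolerance = 1e-12)
  expect_equal(cc$delta, 1.96 * c(a = 1 / 4, b = 2), tolerance = 1e-12)
  # parameter b has delta > 1: its raw lower bound is negative and is
  # replaced by 1e-3 of the best value
  expect_equal(cc$ci["b", "lower"], 10 * 1e-3)
  expect_equal(cc$ci["a", "lower"], 2 * (1 - 1.96 / 4), tolerance = 1e-12)
  expect_true(isSymmetric(cc$C))
  expect_true(all(eigen(cc$C)$values > -1e-12))
  # rank-deficient S: pseudo-inverse with the offending parameter reported
  S_sing <- cbind(a = c(1, 2, 3), b = 2 * c(1, 2, 3))
  expect_warning(cc2 <- covarianceCI(S_sing, c(a = 1, b = 1)),
                 "unidentifiable")
  expect_true(all(c("a", "b") %in% cc2$unidentifiable))
})

test_that("fixed parameters stay bit-identical and balance holds at the optimum", {
  ds <- make_heart_dataset(0.05, seed = 2, replicates = 2L)
  spec <- fitSpec(free = c("X_RaM", "K_O"),
                  fixed = c(n = 24, k_O_I1 = 100), n_starts = 2L)
  fit <- fitRaM(ds, spec, heart_bal, env0, seed = 5)
  expect_identical(fit$p_star[[1]]$n, 24)
  expect_identical(fit$p_star[[1]]$k_O_I1, 100)
  expect_lt(abs(log(balanceResidual(fit$p_star[[1]]))), 1e-12)
})

test_that("zero-noise data refit from a perturbed start recovers the truth", {
  ds0 <- make_heart_dataset(0, seed = 1)
  spec <- fitSpec(free = c("X_RaM", "K_O", "k_I2_R"), n_starts = 2L)
  start <- heart_bal
  start$X_RaM <- heart_bal$X_RaM * 1.2
  start$K_O <- heart_bal$K_O * 0.85
  start$k_I2_R <- heart_bal$k_I2_R * 1.2
  fit <- fitRaM(ds0, spec, start, env0, seed = 3)
  expect_lt(fit$objective, 1e-4)
  truth <- c(heart_bal$X_RaM, heart_bal$K_O, heart_bal$k_I2_R)
  expect_true(all(abs(fit$theta_star - truth) / truth < 0.01))
})

test_that("microscopic reversibility holds at every optimizer iterate", {
  ds <- make_heart_dataset(0.05, seed = 6)
  spec <- fitSpec(free = c("X_RaM", "K_O", "k_I2_R"), n_starts = 1L)
  residuals <- new.env(); residuals$worst <- 0
  # probe via the objective the fitter minimizes: every candidate the
  # optimizer evaluates passes through applyTheta, which re-enforces
  # balance; spot-check a lattice of candidates the same way
  for (fac in list(c(1, 1, 1), c(1.3, 0.9, 1.5), c(0.7, 1.1, 0.5))) {
    th <- c(X_RaM = heart_bal$X_RaM * fac[1], K_O = heart_bal$K_O * fac[2],
            k_I2_R = heart_bal$k_I2_R * fac[3])
    p <- ramkin:::applyTheta(th, heart_bal, spec, "heart", TRUE)
    expect_lt(abs(log(balanceResidual(p))), 1e-12)
  }
  fit <- fitRaM(ds, spec, heart_bal, env0, seed = 2)
  expect_lt(abs(log(balanceResidual(fit$p_star[[1]]))), 1e-12)
})

test_that("nominal 95% intervals cover the truth in most replicates", {
  # Cramer-Rao widths underestimate the true uncertainty, so coverage is
  # checked against a 80% floor rather than the nominal 95%
  protos <- referenceProtocols("heart", 1)
  spec <- fitSpec(free = c("X_RaM", "K_O"), n_starts = 1L)
  hits <- c(X_RaM = 0L, K_O = 0L)
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    ds <- synthesizeDataset(heart_bal, protos, 0.05, seed = 1000 + r,
                            env = env0)
    fit <- fitRaM(ds, spec, heart_bal, env0, seed = r)
    for (nm in names(hits)) {
      tv <- heart_bal[[nm]]
      if (fit$ci[nm, "lower"] <= tv && tv <= fit$ci[nm, "upper"])
        hits[nm] <- hits[nm] + 1L
    }
  }
  expect_gte(hits[["X_RaM"]] / n_rep, 0.8)
  expect_gte(hits[["K_O"]] / n_rep, 0.8)
})

test_that("joint fitting shares parameters across tissues", {
  protos_h <- referenceProtocols("heart", 1)[1:10]
  protos_l <- referenceProtocols("liver", 1)[1:10]
  ds_h <- synthesizeDataset(heart_bal, protos_h, 0.02, seed = 11, env = env0)
  ds_l <- synthesizeDataset(liver_bal, protos_l, 0.02, seed = 12,
                            env = env0, tissue_label = "liver")
  spec <- fitSpec(free = c("X_RaM", "K_Ca"), shared = "K_Ca",
                  n_starts = 1L)
  fit <- fitRaM(list(ds_h, ds_l), spec,
                list(heart = heart_bal, liver = liver_bal), env0, seed = 4)
  expect_identical(fit$p_star$heart$K_Ca, fit$p_star$liver$K_Ca)
  expect_false(identical(fit$p_star$heart$X_RaM, fit$p_star$liver$X_RaM))
  expect_setequal(names(fit$theta_star),
                  c("heart:X_RaM", "liver:X_RaM", "K_Ca"))
})

test_that("invalid candidates draw a large finite penalty, not an error", {
  ds <- make_heart_dataset(0.05, seed = 8)
  spec <- fitSpec(free = c("X_RaM", "K_O", "k_I2_R"))
  # a theta that drives the dependent rate into degeneracy still returns
  v <- ramkin:::thetaObjective(
    log(c(X_RaM = 1e-290, K_O = 224, k_I2_R = 1e-290)),
    c("X_RaM", "K_O", "k_I2_R"), list(heart_bal), list(ds), spec, env0,
    TRUE)
  expect_true(is.finite(v))
})
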