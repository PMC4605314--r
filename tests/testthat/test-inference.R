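test_that("fit_trace inverts a noiseless bi-exponential to <= 0.1%", {
  truth <- relaxation_params(0.12, 0.03, 0.05, 0.1, 0.01)
  ft <- fit_trace(biexp_trace(truth))
  expect_true(ft$converged)
  expect_true(ft$modes_resolved)
  expect_equal(unname(coef(ft)), unname(unlist(truth[1:5])), tolerance = 1e-3)
  expect_lt(ft$residual_rms, 1e-8)
})

test_that("fit_trace recovers both rates from noisy replicates (median within 10%)", {
  truth <- relaxation_params(0.12, 0.03, 0.05, 0.1, 0.01)
  tt <- seq(1, 600)
  clean <- biexp_extension(truth, tt)
  est <- t(vapply(1:50, function(i) {
    set.seed(1000 + i)
    tr <- threading_trace(tt, clean + rnorm(600, sd = 0.002), 20, 5)
    coef(fit_trace(tr))[c("k_f", "k_s")]
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) / 0.1 - 1), 0.1)
  expect_lt(abs(median(est[, 2]) / 0.01 - 1), 0.1)
})

test_that("fit_trace flags a single-exponential truth instead of inventing a mode", {
  truth <- relaxation_params(0.1, 0, 0.08, 0.02, 0.02)
  tt <- seq(1, 600)
  set.seed(4)
  tr <- threading_trace(tt, biexp_extension(truth, tt) + rnorm(600, sd = 0.002),
                        20, 5)
  ft <- fit_trace(tr)
  # acceptable outcomes: the fast amplitude is flagged as consistent with
  # zero, is negligibly small, or the two modes are flagged unresolved --
  # never two confidently distinct rates
  expect_true(ft$single_mode || !ft$modes_resolved || ft$params$dx_f < 0.01)
})

test_that("fit_trace rejects traces with the wrong sign convention", {
  tt <- seq(1, 100)
  tr <- threading_trace(tt, 0.1 * exp(-0.05 * tt), 20, 5)
  expect_error(fit_trace(tr), "decreases")
  expect_error(fit_trace(threading_trace(1:10, rep(0, 10), 20, 5)),
               "at least 20")
})

test_that("decompose_rates inverts noiseless pre-equilibrium data to <= 0.1%", {
  truth <- fx$rates0
  C <- c(1, 3, 5, 7)
  ob <- observed_rates_preequilibrium(truth, C)
  ser <- data.frame(concentration = C, k_f = ob$k_f, k_s = ob$k_s)
  for (m in c("two_stage", "joint")) {
    dec <- decompose_rates(ser, method = m, quiet = TRUE)
    expect_equal(dec$k1, truth$k1, tolerance = 1e-3)
    expect_equal(dec$k_m1, truth$k_m1, tolerance = 1e-3)
    expect_equal(dec$k2, truth$k2, tolerance = 1e-3)
    expect_equal(dec$k_m2, truth$k_m2, tolerance = 1e-3)
  }
  # the exact method inverts exact eigenrate data
  oe <- observed_rates_exact(truth, C)
  sere <- data.frame(concentration = C, k_f = oe$lambda_fast,
                     k_s = oe$lambda_slow)
  dece <- decompose_rates(sere, method = "exact", quiet = TRUE)
  expect_equal(dece$k1, truth$k1, tolerance = 1e-4)
  expect_equal(dece$k_m2, truth$k_m2, tolerance = 1e-4)
})

test_that("decompose_rates survives multiplicative rate noise (median within 25%)", {
  truth <- fx$rates0
  C <- c(1, 3, 5, 7)
  ob <- observed_rates_preequilibrium(truth, C)
  est <- t(vapply(1:100, function(i) {
    set.seed(2000 + i)
    ser <- data.frame(concentration = C,
                      k_f = ob$k_f * exp(rnorm(4, sd = 0.1)),
                      k_s = ob$k_s * exp(rnorm(4, sd = 0.1)))
    dec <- decompose_rates(ser, method = "two_stage", quiet = TRUE)
    c(dec$k1, dec$k_m1, dec$k2, dec$k_m2)
  }, numeric(4)))
  tru <- unlist(truth[c("k1", "k_m1", "k2", "k_m2")])
  rel <- abs(apply(est, 2, median) / tru - 1)
  # the off rates dominate the observed rates at 1-7 nM and are recovered
  # tightly; the forward rates ride on small concentration-dependent
  # differences and carry a larger noise-induced distortion
  expect_lt(rel[2], 0.25)
  expect_lt(rel[4], 0.25)
  expect_lt(rel[1], 0.35)
  expect_lt(rel[3], 0.35)
})

test_that("decompose_rates handles a concentration-independent slow rate", {
  truth <- elementary_rates(1.8e-3, 68e-3, 0, 3.6e-3)
  C <- c(1, 3, 5, 7)
  ob <- observed_rates_preequilibrium(truth, C)
  dec <- decompose_rates(data.frame(concentration = C, k_f = ob$k_f,
                                    k_s = ob$k_s), quiet = TRUE)
  expect_lt(dec$k2, 1e-10)
})

test_that("decompose_rates is invariant to ordering and uncertainty rescaling", {
  truth <- fx$rates0
  C <- c(1, 3, 5, 7)
  ob <- observed_rates_preequilibrium(truth, C)
  set.seed(9)
  ser <- data.frame(concentration = C,
                    k_f = ob$k_f * exp(rnorm(4, sd = 0.05)),
                    k_s = ob$k_s * exp(rnorm(4, sd = 0.05)),
                    se_k_f = c(2e-3, 1e-3, 3e-3, 2e-3),
                    se_k_s = c(2e-4, 1e-4, 3e-4, 2e-4))
  d1 <- decompose_rates(ser, quiet = TRUE)
  d2 <- decompose_rates(ser[c(3, 1, 4, 2), ], quiet = TRUE)
  d3 <- decompose_rates(transform(ser, se_k_f = 7 * se_k_f,
                                  se_k_s = 7 * se_k_s), quiet = TRUE)
  expect_equal(unlist(d1[1:4]), unlist(d2[1:4]), tolerance = 1e-10)
  expect_equal(unlist(d1[1:4]), unlist(d3[1:4]), tolerance = 1e-10)
  expect_error(decompose_rates(ser[1:2, ], quiet = TRUE), "3 distinct")
})

test_that("fit_force_dependence is the closed-form log-space regression", {
  truth <- bell_params(5.8e-3, 0.08)
  f <- c(20, 30, 50)
  k <- bell_rate(truth, f)
  fit <- fit_force_dependence(f, k)
  expect_equal(coef(fit)[["k0"]], 5.8e-3, tolerance = 1e-9)
  expect_equal(coef(fit)[["x_dagger"]], 0.08, tolerance = 1e-9)
  # closed-form simple-regression oracle
  lx <- log(k)
  slope <- sum((f - mean(f)) * (lx - mean(lx))) / sum((f - mean(f))^2)
  intercept <- mean(lx) - slope * mean(f)
  expect_equal(coef(fit)[["x_dagger"]], slope * 4.05, tolerance = 1e-12)
  expect_equal(coef(fit)[["k0"]], exp(intercept), tolerance = 1e-12)
})

test_that("fit_force_dependence sign and degenerate behaviour", {
  # rates decreasing with force give a negative transition distance
  km2 <- bell_params(3.6e-3, -0.15)
  f <- c(20, 30, 50)
  fit <- fit_force_dependence(f, bell_rate(km2, f))
  expect_lt(coef(fit)[["x_dagger"]], 0)
  # constant rates give zero distance
  fit0 <- fit_force_dependence(f, rep(2e-3, 3))
  expect_equal(coef(fit0)[["x_dagger"]], 0, tolerance = 1e-12)
  expect_error(fit_force_dependence(f, c(1e-3, 0, 1e-3)), "positive")
  expect_error(fit_force_dependence(f[1:2], c(1, 2)), "at least 3")
})

test_that("equilibrium route inverts noiseless isotherm and ratio data", {
  C <- c(1, 3, 5, 7, 20)
  d <- data.frame(force = 20, concentration = C,
                  theta = (C / 4.1) / (C / 4.1 + 1),
                  amp_ratio = amplitude_ratio(C, 11))
  er <- equilibrium_route(d)
  expect_equal(er$per_force$Kd, 4.1, tolerance = 1e-6)
  expect_equal(er$per_force$Kd1, 11, tolerance = 1e-6)
  expect_equal(er$per_force$K2, 11 / 4.1, tolerance = 1e-6)
  expect_null(er$laws)  # one force cannot be extrapolated
})

test_that("equilibrium route flags unidentifiable saturation and recovers force laws", {
  # all-saturated occupancies cannot pin Kd
  C <- c(1, 3, 5)
  dbad <- data.frame(force = 20, concentration = C, theta = 1,
                     amp_ratio = amplitude_ratio(C, 11))
  er <- equilibrium_route(dbad)
  expect_false(er$per_force$identifiable)

  lawKd <- force_law(4.1, 0.33)
  lawKd1 <- force_law(11, 0.25)
  C <- c(1, 3, 5, 7, 20)
  d <- do.call(rbind, lapply(c(20, 30, 50), function(f) {
    Kd <- equilibrium_force_law_eval(lawKd, f)
    Kd1 <- equilibrium_force_law_eval(lawKd1, f)
    data.frame(force = f, concentration = C,
               theta = (C / Kd) / (C / Kd + 1),
               amp_ratio = amplitude_ratio(C, Kd1))
  }))
  er <- equilibrium_route(d)
  expect_equal(er$laws$Kd$K0, 4.1, tolerance = 1e-5)
  expect_equal(er$laws$Kd$x0, 0.33, tolerance = 1e-5)
  expect_equal(er$laws$Kd1$K0, 11, tolerance = 1e-5)
  expect_equal(er$laws$K2$K0, 11 / 4.1, tolerance = 1e-5)
  # K2 = Kd1/Kd identity per force
  expect_equal(er$per_force$K2, er$per_force$Kd1 / er$per_force$Kd,
               tolerance = 1e-12)
})

test_that("consistency report mirrors the two-column zero-force comparison", {
  rep0 <- consistency_report(fx$kinetic[c("Kd", "Kd1", "K2")],
                             fx$equilibrium[c("Kd", "Kd1", "K2")])
  expect_equal(rep0$kinetic, c(15, 35, 1.8))
  expect_equal(rep0$equilibrium, c(4.1, 11, 2.7))
  # the overall Kd is roughly half the first-step Kd1 in both routes
  expect_lt(abs(fx$kinetic$Kd / fx$kinetic$Kd1 - 0.5), 0.15)
  expect_lt(abs(fx$equilibrium$Kd / fx$equilibrium$Kd1 - 0.5), 0.15)
  ident <- consistency_report(list(Kd = 2, K2 = 3), list(Kd = 2, K2 = 3))
  expect_equal(ident$ratio, c(1, 1))
})

test_that("fit_global_bell inverts noiseless eigenrate grids", {
  grid <- expand.grid(concentration = c(1, 3, 5, 7), force = c(20, 30, 50))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- rates_at_force(fx$bells, grid$force[i])
    ob <- observed_rates_exact(r, grid$concentration[i])
    data.frame(force = grid$force[i], concentration = grid$concentration[i],
               k_f = ob$lambda_fast, k_s = ob$lambda_slow)
  })
  gb <- fit_global_bell(do.call(rbind, rows))
  expect_equal(gb$rates0$k1, fx$rates0$k1, tolerance = 1e-6)
  expect_equal(gb$rates0$k_m2, fx$rates0$k_m2, tolerance = 1e-6)
  expect_equal(unname(gb$distances), unname(fx$distances), tolerance = 1e-6)
})

test_that("two-stage pre-equilibrium decomposition is measurably biased when the separation is marginal", {
  # noiseless pipeline: any error is systematic, from the pre-equilibrium
  # approximation applied to exact eigenrates at low force and concentration
  sim0 <- simulate_experiment(seed = 11, noise_sd = 0)
  tru <- unlist(fx$rates0[c("k1", "k_m1", "k2", "k_m2")])
  an_ts <- suppressWarnings(analyze_experiment(sim0$traces,
                                               decomposition = "two_stage",
                                               quiet = TRUE))
  err_ts <- abs(unlist(an_ts$rates0[c("k1", "k_m1", "k2", "k_m2")]) / tru - 1)
  expect_gt(max(err_ts), 0.1)   # the approximation bias is real ...
  expect_lt(max(err_ts), 0.5)   # ... but bounded
  an_ex <- suppressWarnings(analyze_experiment(sim0$traces,
                                               decomposition = "exact",
                                               quiet = TRUE))
  err_ex <- abs(unlist(an_ex$rates0[c("k1", "k_m1", "k2", "k_m2")]) / tru - 1)
  expect_lt(max(err_ex), 1e-6)  # the exact decomposition removes it
})
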