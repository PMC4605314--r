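test_that("noiseless mean-field trace equals the closed-form bi-exponential to 1e-9", {
  cfg <- simulation_config(force = 20, concentration = 5, noise_sd = 0,
                           seed = 1)
  tr <- simulate_trace(cfg)
  r <- rates_at_force(fx$bells, 20)
  dxs <- dx_sat_at_force(fx$flexRu2_sat, fx$dsDNA, 20)
  p <- relaxation_from_scheme(r, 5, dxs)
  expect_lt(max(abs(tr$dx - biexp_extension(p, tr$time))), 1e-9)
})

test_that("no ligand means a flat zero trace", {
  cfg <- simulation_config(force = 20, concentration = 0, noise_sd = 0,
                           seed = 2, duration = 60)
  expect_true(all(simulate_trace(cfg)$dx == 0))
})

test_that("identical configuration and seed give bit-identical traces", {
  for (backend in c("meanfield", "gillespie")) {
    cfg <- simulation_config(force = 30, concentration = 3, noise_sd = 0.002,
                             seed = 77, duration = 120, backend = backend,
                             n_sites = 500)
    expect_identical(simulate_trace(cfg)$dx, simulate_trace(cfg)$dx)
  }
})

test_that("drift adds the configured linear trend", {
  base <- simulation_config(force = 20, concentration = 5, noise_sd = 0,
                            seed = 3, duration = 100)
  drift <- simulation_config(force = 20, concentration = 5, noise_sd = 0,
                             seed = 3, duration = 100, drift_rate = 1e-5)
  d <- simulate_trace(drift)$dx - simulate_trace(base)$dx
  expect_equal(d, 1e-5 * seq_len(100), tolerance = 1e-12)
})

test_that("simulated equilibrium approaches the isotherm occupancy of the scheme", {
  cfg <- simulation_config(force = 50, concentration = 7, noise_sd = 0,
                           seed = 5, duration = 3000)
  tr <- simulate_trace(cfg)
  r <- rates_at_force(fx$bells, 50)
  eq <- equilibrium_from_rates(r)
  dxs <- dx_sat_at_force(fx$flexRu2_sat, fx$dsDNA, 50)
  theta_end <- tail(tr$dx, 1) / dxs
  theta_iso <- (7 / eq$Kd) / (7 / eq$Kd + 1)
  # the scheme's readout includes the half-length mono state, so agreement
  # with the two-state isotherm is approximate
  expect_lt(abs(theta_end - theta_iso), 0.05)
})

test_that("stochastic site counts are conserved and converge to the mean field", {
  cfg <- simulation_config(force = 20, concentration = 5, noise_sd = 0,
                           seed = 11, duration = 300, backend = "gillespie",
                           n_sites = 100000)
  r <- rates_at_force(fx$bells, 20)
  set.seed(11)
  counts <- threadkin:::gillespie_counts(1000, r$k1 * 5, r$k_m1, r$k2, r$k_m2,
                                         as.numeric(1:300))
  expect_true(all(counts >= 0))
  expect_true(all(rowSums(counts) == 1000))

  trg <- simulate_trace(cfg)
  cfgm <- simulation_config(force = 20, concentration = 5, noise_sd = 0,
                            seed = 11, duration = 300)
  trm <- simulate_trace(cfgm)
  # per-site readout variance is bounded by 0.25 (values in [0, 1]),
  # so 3 standard errors of the site average is 3 * 0.5 / sqrt(n)
  bound <- 3 * 0.5 * dx_sat_at_force(fx$flexRu2_sat, fx$dsDNA, 20) / sqrt(1e5)
  dec <- seq(10, 300, by = 10)
  expect_true(all(abs(trg$dx[dec] - trm$dx[dec]) < bound))
})

test_that("saturated curves round-trip through the WLC fit", {
  d0 <- simulate_saturated_curve(fx$flexRu2_sat)
  expect_equal(d0$extension, wlc_extension(fx$flexRu2_sat, d0$force))
  fit <- fit_wlc(d0$force, d0$extension)
  expect_equal(unname(coef(fit)), c(0.49, 2.9, 800), tolerance = 1e-3)
  expect_error(simulate_saturated_curve(fx$flexRu2_sat, forces = c(0, 10)),
               "positive")
})

test_that("packaged parameter fixtures carry the reference values", {
  expect_equal(fx$rates0$k1, 1.8e-3)
  expect_equal(fx$rates0$k_m1, 68e-3)
  expect_equal(fx$dsDNA$persistence, 47)
  expect_equal(fx$distances[["k_m2"]], -0.15)
  expect_equal(fx$kinetic$Kd, 15)
  expect_equal(fx$equilibrium$K2, 2.7)
  b <- fx$binding
  expect_equal(b$kinetic_se[b$parameter == "k_m1"], 4e-3)
})

test_that("simulate_experiment writes a reproducible condition grid", {
  dir1 <- withr::local_tempdir()
  out <- simulate_experiment(seed = 42, dir = dir1, duration = 30,
                             noise_sd = 0.002)
  expect_length(out$traces, 12)
  expect_setequal(unique(out$manifest$force), c(20, 30, 50))
  expect_setequal(unique(out$manifest$concentration), c(1, 3, 5, 7))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # same master seed reproduces the same files bit for bit
  dir2 <- withr::local_tempdir()
  out2 <- simulate_experiment(seed = 42, dir = dir2, duration = 30,
                              noise_sd = 0.002)
  expect_identical(unname(out$manifest$md5), unname(out2$manifest$md5))
})
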