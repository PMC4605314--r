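test_that("pre-equilibrium observed rates follow the closed forms", {
  r <- fx$rates0
  ob <- observed_rates_preequilibrium(r, 3)
  expect_equal(ob$k_f, 1.8e-3 * 3 + 68e-3, tolerance = 1e-12)      # 0.0734
  expect_equal(ob$k_s, 5.8e-3 * (5.4e-3 / 0.0734) + 3.6e-3,
               tolerance = 1e-12)                                   # ~4.03e-3
  # no association flux at C = 0
  ob0 <- observed_rates_preequilibrium(r, 0)
  expect_equal(ob0$k_f, r$k_m1)
  expect_equal(ob0$k_s, r$k_m2)
  # saturated pre-equilibrium factor at large C
  obi <- observed_rates_preequilibrium(r, 1e9)
  expect_equal(obi$k_s, r$k2 + r$k_m2, tolerance = 1e-6)
  expect_error(observed_rates_preequilibrium(elementary_rates(1e-3, 0, 1, 1), 0),
               "undefined")
})

test_that("exact eigenrates match an independent eigendecomposition", {
  for (r in random_rates(20, seed = 11)) {
    for (C in c(0, 1, 10)) {
      ob <- observed_rates_exact(r, C)
      kon <- r$k1 * C
      J <- matrix(c(-(kon + r$k_m1 + r$k2), r$k_m2 - kon,
                    r$k2, -r$k_m2), 2, 2, byrow = TRUE)
      lam <- sort(-Re(eigen(J)$values), decreasing = TRUE)
      expect_equal(ob$lambda_fast, lam[1], tolerance = 1e-9)
      expect_equal(ob$lambda_slow, lam[2], tolerance = 1e-6)
    }
  }
})

test_that("exact eigenrates: special cases and trace/determinant identities", {
  # first step only
  r1 <- elementary_rates(2e-3, 5e-2, 0, 0)
  ob <- observed_rates_exact(r1, 4)
  expect_equal(ob$lambda_fast, 2e-3 * 4 + 5e-2)
  expect_equal(ob$lambda_slow, 0)
  # fully symmetric unit-rate case (hand algebra on the quadratic)
  rs <- elementary_rates(1, 1, 1, 1)
  obs <- observed_rates_exact(rs, 1)
  expect_equal(obs$lambda_fast, 3)
  expect_equal(obs$lambda_slow, 1)
  # sum and product identities over random rate sets
  for (r in random_rates(25, seed = 7)) {
    C <- 3
    ob <- observed_rates_exact(r, C)
    a <- r$k1 * C + r$k_m1
    S <- a + r$k2 + r$k_m2
    P <- r$k1 * C * (r$k2 + r$k_m2) + r$k_m1 * r$k_m2
    expect_equal(ob$lambda_fast + ob$lambda_slow, S, tolerance = 1e-12)
    expect_equal(ob$lambda_fast * ob$lambda_slow, P, tolerance = 1e-9)
    expect_gte(ob$lambda_slow, 0)
  }
})

test_that("pre-equilibrium formulas agree with the exact eigenrates when the ratio is large", {
  found <- 0
  for (r in random_rates(300, seed = 23)) {
    C <- 5
    ratio <- preequilibrium_ratio(r, C, quiet = TRUE)
    if (ratio < 10) next
    found <- found + 1
    pe <- observed_rates_preequilibrium(r, C)
    ex <- observed_rates_exact(r, C)
    expect_lt(abs(pe$k_f / ex$lambda_fast - 1), 0.1)
    if (ex$lambda_slow > 0)
      expect_lt(abs(pe$k_s / ex$lambda_slow - 1), 0.1)
  }
  expect_gt(found, 30)  # the draw actually exercises the regime
})

test_that("pre-equilibrium ratio diagnostics", {
  expect_equal(preequilibrium_ratio(fx$rates0, 0, quiet = TRUE), 68 / 9.4,
               tolerance = 1e-12)
  expect_warning(preequilibrium_ratio(fx$rates0, 0), "marginal")
  r0 <- elementary_rates(1e-3, 2e-2, 0, 0)
  expect_identical(preequilibrium_ratio(r0, 5, quiet = TRUE), Inf)
  rk <- elementary_rates(0, 3e-2, 1e-3, 1e-3)
  expect_equal(preequilibrium_ratio(rk, 100, quiet = TRUE), 3e-2 / 2e-3)
})

test_that("bell_rate evaluates the exponential force law", {
  bp <- bell_params(68e-3, -0.06)
  expect_equal(bell_rate(bp, 0), 68e-3)
  expect_equal(bell_rate(bp, 20), 68e-3 * exp(-20 * 0.06 / 4.05),
               tolerance = 1e-12)  # ~0.0506 s^-1
  bp2 <- bell_params(1.8e-3, 0.19)
  expect_equal(bell_rate(bp2, 50), 1.8e-3 * exp(50 * 0.19 / 4.05),
               tolerance = 1e-12)
  # increasing in F iff the transition distance is positive
  expect_gt(bell_rate(bp2, 30), bell_rate(bp2, 20))
  expect_lt(bell_rate(bp, 30), bell_rate(bp, 20))
})

test_that("equilibrium constants from rates satisfy their defining identities", {
  eq <- equilibrium_from_rates(fx$rates0)
  expect_equal(eq$Kd1, 68 / 1.8, tolerance = 1e-12)        # ~37.8 nM
  expect_equal(eq$K2, 5.8 / 3.6, tolerance = 1e-12)        # ~1.61
  expect_equal(eq$Kd, eq$Kd1 / eq$K2, tolerance = 1e-12)   # ~23.4 nM
  expect_equal(eq$Kd * eq$K2, eq$Kd1)                      # detailed balance
  # infinitely tight first step
  expect_equal(equilibrium_from_rates(elementary_rates(1e-3, 0, 1e-3, 1e-3))$Kd1, 0)
  expect_error(equilibrium_from_rates(elementary_rates(0, 1e-2, 1e-3, 1e-3)),
               "forward")
})

test_that("equilibrium force law evaluation and its Bell-consistency", {
  law <- force_law(15, 0.44)
  expect_equal(equilibrium_force_law_eval(law, 0), 15)
  expect_equal(equilibrium_force_law_eval(law, 20), 15 * exp(-20 * 0.44 / 4.05),
               tolerance = 1e-12)
  expect_equal(equilibrium_force_law_eval(force_law(7, 0), c(0, 25, 50)),
               rep(7, 3))
  # K(F) built from two Bell laws with x0 = x_plus - x_minus
  kp <- bell_params(1.8e-3, 0.19)
  km <- bell_params(68e-3, -0.06)
  law1 <- force_law(km$k0 / kp$k0, step_elongation(kp$x_dagger, km$x_dagger))
  for (f in c(5, 20, 30, 50))
    expect_equal(bell_rate(km, f) / bell_rate(kp, f),
                 equilibrium_force_law_eval(law1, f), tolerance = 1e-12)
})

test_that("step elongations from the fitted transition distances", {
  expect_equal(step_elongation(0.19, -0.06), 0.25)
  expect_equal(step_elongation(0.08, -0.15), 0.23)
  expect_equal(step_elongation(0.3, 0.3), 0)
})

test_that("rates_at_force scales all four rates with the Bell laws", {
  r20 <- rates_at_force(fx$bells, 20)
  expect_equal(r20$k1, bell_rate(fx$bells$k1, 20))
  expect_equal(r20$k_m2, bell_rate(fx$bells$k_m2, 20))
  expect_equal(r20$force, 20)
  expect_error(rates_at_force(fx$bells[1:3], 20), "must contain")
})
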