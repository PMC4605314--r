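test_that("landscape reproduces the reference elongations and energies", {
  l15 <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                         concentration = 15)
  expect_equal(l15$elongation, c(0, 0.19, 0.25, 0.33, 0.48), tolerance = 1e-12)
  g <- function(l, lab) l$energy[l$label == lab]
  # C = Kd levels the non- and bis-intercalated minima
  expect_equal(g(l15, "non"), 0, tolerance = 1e-12)
  expect_equal(g(l15, "bis"), 0)
  # first barrier: ln(1 / (k1 C)) = -ln(15 * 1.8e-3) ~ 3.6 kBT
  expect_equal(g(l15, "TS1"), -log(15 * 1.8e-3), tolerance = 1e-12)
  expect_equal(round(g(l15, "TS1"), 1), 3.6)
  # mono minimum under the dissociation-constant ratio convention
  expect_equal(g(l15, "mono"), log(35 / 15), tolerance = 1e-12)
  expect_equal(round(g(l15, "mono"), 2), 0.85)

  l35 <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                         concentration = 35)
  expect_equal(round(g(l35, "non"), 2), 0.85)

  # K2-convention mono minimum: ln(1.8) ~ 0.59 kBT
  lk2 <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                         concentration = 15, mono_convention = "K2", K2 = 1.8)
  expect_equal(round(g(lk2, "mono"), 2), 0.59)
})

test_that("barrier heights follow the attempt-rate convention", {
  l <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                       concentration = 15)
  # second forward barrier from k2 = 5.8e-3 at attempt rate 1/s
  expect_equal(barrier_heights(l, "mono", "forward"), -log(5.8e-3),
               tolerance = 1e-12)
  expect_equal(round(barrier_heights(l, "mono", "forward"), 1), 5.1)
  expect_equal(barrier_from_rate(5.8e-3), -log(5.8e-3))
  # reverse-second barrier measured from the mono state:
  # -ln(k_m2) - ln(Kd1/Kd) = 5.63 - 0.85 ~ 4.8 kBT
  rev2 <- barrier_from_rate(3.6e-3) - l$energy[l$label == "mono"]
  expect_equal(round(barrier_from_rate(3.6e-3), 2), 5.63)
  expect_equal(round(rev2, 1), 4.8)
  expect_error(barrier_heights(l, "non", "reverse"), "no reverse")
  expect_error(barrier_heights(l, "bis", "forward"), "no forward")
})

test_that("rates rebuilt from barriers reproduce the inputs (duality)", {
  # self-consistent constants from the rates themselves
  eq <- equilibrium_from_rates(fx$rates0)
  C <- 5
  l <- build_landscape(fx$rates0, fx$distances, Kd = eq$Kd, Kd1 = eq$Kd1,
                       concentration = C)
  k0a <- attr(l, "attempt_rate")
  expect_equal(k0a * exp(-barrier_heights(l, "non", "forward")),
               fx$rates0$k1 * C, tolerance = 1e-9)
  expect_equal(k0a * exp(-barrier_heights(l, "mono", "reverse")),
               fx$rates0$k_m1, tolerance = 1e-9)
  expect_equal(k0a * exp(-barrier_heights(l, "mono", "forward")),
               fx$rates0$k2, tolerance = 1e-9)
  expect_equal(k0a * exp(-barrier_heights(l, "bis", "reverse")),
               fx$rates0$k_m2, tolerance = 1e-9)
  # thermodynamic closure
  g <- function(lab) l$energy[l$label == lab]
  expect_equal((g("mono") - g("non")) + (0 - g("mono")), -g("non"))
  expect_equal(g("non"), log(C / eq$Kd), tolerance = 1e-12)
})

test_that("concentration shifts only the non-intercalated minimum", {
  la <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                        concentration = 15)
  lb <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                        concentration = 35)
  keep <- c("TS1", "mono", "TS2", "bis")
  expect_equal(la$energy[la$label %in% keep], lb$energy[lb$label %in% keep],
               tolerance = 1e-12)
  expect_equal(lb$energy[lb$label == "non"] - la$energy[la$label == "non"],
               log(35 / 15), tolerance = 1e-12)
})

test_that("doubling the attempt rate raises every barrier by ln 2", {
  l1 <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                        concentration = 15, attempt_rate = 1)
  l2 <- build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
                        concentration = 15, attempt_rate = 2)
  for (from in c("non", "mono")) {
    expect_equal(barrier_heights(l2, from, "forward") -
                   barrier_heights(l1, from, "forward"), log(2),
                 tolerance = 1e-12)
  }
  # minima unchanged
  mins <- c("non", "mono", "bis")
  expect_equal(l1$energy[l1$label %in% mins], l2$energy[l2$label %in% mins])
})

test_that("non-increasing elongations are rejected", {
  bad <- fx$distances
  bad[["k_m1"]] <- 0.25  # makes x1 negative
  expect_error(build_landscape(fx$rates0, bad, 15, 35, 15), "non-increasing")
})
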