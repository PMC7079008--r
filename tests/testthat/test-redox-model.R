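test_that("rate equations follow the mass-action law", {
  # null mechanism
  d0 <- rate_equations(system_state(ss = 1, sh = 2, red = 3, o2 = 0.5),
                       rate_constants())
  expect_true(all(d0 == 0))

  # unit second-order reduction
  d1 <- rate_equations(system_state(ss = 1, red = 2), rate_constants(k1 = 1))
  expect_equal(unname(d1[c("ss", "sh", "red", "ox")]), c(-2, 2, -2, 2))
  expect_equal(unname(d1[c("o2", "precipitated")]), c(0, 0))

  # reoxidation + oxygen ingress, hand-evaluated
  d2 <- rate_equations(system_state(sh = 2, o2 = 0.1),
                       rate_constants(k2 = 0.5, k4 = 0.02))
  expect_equal(d2[["ss"]], 0.1)
  expect_equal(d2[["sh"]], -0.1)
  expect_equal(d2[["o2"]], -0.08)
})

test_that("invalid states and rate constants are rejected", {
  expect_error(rate_constants(k1 = -1), "finite")
  expect_error(rate_constants(k1 = NaN), "finite")
  expect_error(system_state(ss = -0.1), "finite")
})

test_that("simulation with all rates zero is constant", {
  init <- system_state(ss = 1.7, sh = 0.2, red = 3.4, o2 = 0.25)
  tc <- simulate_redox(rate_constants(), init, seq(0, 100, length.out = 11))
  for (nm in c("ss", "sh", "red", "ox", "o2", "precipitated")) {
    expect_equal(tc[[nm]], rep(unclass(init)[[nm]], 11))
  }
})

test_that("integrated reduction matches the closed-form second-order oracle", {
  k1 <- 0.259; ss0 <- 1.7; red0 <- 3.4
  times <- seq(0, 20, length.out = 100)
  tc <- simulate_redox(rate_constants(k1 = k1),
                       system_state(ss = ss0, red = red0), times)
  # independent oracle: analytic solution of the second-order rate law
  oracle <- ss0 * (red0 - ss0) / (red0 * exp(k1 * (red0 - ss0) * times) - ss0)
  expect_equal(tc$ss, oracle, tolerance = 1e-6)
  expect_lt(max(abs(tc$ss - oracle) / oracle), 1e-6)
  # spot value at t = 0.921 min
  tc2 <- simulate_redox(rate_constants(k1 = k1),
                        system_state(ss = ss0, red = red0), c(0, 0.921))
  expect_equal(tc2$ss[2], 0.8497, tolerance = 1e-3)
})

test_that("pure precipitation decays exponentially into the precipitated pool", {
  k3 <- 0.05; sh0 <- 0.8
  times <- seq(0, 100, length.out = 50)
  tc <- simulate_redox(rate_constants(k3 = k3), system_state(sh = sh0), times)
  expect_equal(tc$sh, sh0 * exp(-k3 * times), tolerance = 1e-7)
  expect_equal(tc$precipitated, sh0 - tc$sh, tolerance = 1e-7)
})

test_that("mass is conserved over long horizons with the full mechanism", {
  init <- system_state(ss = 1.0, sh = 0.1, red = 2.5, o2 = 0.2)
  tc <- simulate_redox(rate_constants(k1 = 5e-3, k2 = 2e-3, k3 = 1e-4, k4 = 5e-5),
                       init, c(0, 10^seq(0, 4, length.out = 40)))
  protein <- tc$ss + tc$sh + tc$precipitated
  agent <- tc$red + tc$ox
  expect_lt(max(abs(protein - protein[1])) / protein[1], 1e-6)
  expect_lt(max(abs(agent - agent[1])) / agent[1], 1e-6)
  expect_equal(unname(unlist(tc[1, -1])), unname(unclass(init)))
})

test_that("monotonicity: ss non-increasing without reoxidation, o2 non-decreasing with ingress only", {
  tc <- simulate_redox(rate_constants(k1 = 1e-2, k3 = 1e-3),
                       system_state(ss = 1, red = 2), seq(0, 500, 5))
  expect_true(all(diff(tc$ss) <= 1e-12))
  tc2 <- simulate_redox(rate_constants(k4 = 1e-3),
                        system_state(ss = 1, o2 = 0.1), seq(0, 100, 1))
  expect_true(all(diff(tc2$o2) >= -1e-12))
})

test_that("optional oxygen saturation cap halts ingress", {
  tc <- simulate_redox(rate_constants(k4 = 1e-2), system_state(o2 = 0),
                       seq(0, 100, 1), o2_sat = 0.3)
  expect_lt(max(tc$o2), 0.3 + 1e-6)
  tc_free <- simulate_redox(rate_constants(k4 = 1e-2), system_state(o2 = 0),
                            seq(0, 100, 1))
  expect_equal(max(tc_free$o2), 1, tolerance = 1e-6)
})

test_that("half-life follows the second-order case rules", {
  # 18-fold excess of reducing agent: direct evaluation of the formula
  expect_equal(half_life(8.03e-4, 0.113, 2.034),
               log(2 - 0.113 / 2.034) / (8.03e-4 * (2.034 - 0.113)),
               tolerance = 1e-12)
  expect_equal(half_life(8.03e-4, 0.113, 2.034), 431.09, tolerance = 1e-4)
  # symmetric limit
  expect_equal(half_life(1, 1, 1), 1.0)
  # protein in excess but within 2x: swapped formula
  expect_equal(half_life(1, 1.5, 1),
               log(2 - 1 / 1.5) / (1 * (1.5 - 1)), tolerance = 1e-12)
  # reducing agent exhausted before [SS] can halve
  expect_true(is.na(half_life(1, 3, 1)))
  expect_error(half_life(0, 1, 1), "k1")
  expect_error(half_life(1, -1, 1), "concentrations")
})

test_that("half-life is continuous near equal concentrations", {
  expect_equal(half_life(1, 1, 1 + 1e-10), half_life(1, 1, 1), tolerance = 1e-6)
})

test_that("half-life agrees with the simulated half-crossing time", {
  k1 <- 2.71e-4; ss0 <- 1.7; red0 <- 3.4
  t_half <- half_life(k1, ss0, red0)
  times <- seq(0, 2 * t_half, length.out = 4001)
  tc <- simulate_redox(rate_constants(k1 = k1),
                       system_state(ss = ss0, red = red0), times)
  crossing <- stats::approx(tc$ss, times, xout = ss0 / 2)$y
  expect_equal(crossing, t_half, tolerance = 1e-3)
})

test_that("conversion fraction spans 0 to 1 for complete reduction", {
  tc <- simulate_redox(rate_constants(k1 = 1e-2),
                       system_state(ss = 1, red = 10),
                       c(0, 10^seq(-1, 4, length.out = 60)))
  frac <- conversion_fraction(tc)
  expect_equal(frac[1], 0)
  expect_gt(tail(frac, 1), 0.999)
  expect_equal(attr(frac, "n_undefined"), 0)
})

test_that("sustained reoxidation leaves conversion strictly below 1", {
  tc <- simulate_redox(rate_constants(k1 = 1e-2, k2 = 0.5, k4 = 2e-3),
                       system_state(ss = 1, red = 10, o2 = 0.02),
                       seq(0, 1000, length.out = 400))
  frac <- conversion_fraction(tc)
  expect_lt(tail(frac, 1), 0.999)
  expect_gt(tail(frac, 1), 0.5)
})

test_that("the three kinetic regimes are reproduced and classified", {
  # stage I: reduction still dominating mid-course
  tcI <- simulate_redox(rate_constants(k1 = 1e-2),
                        system_state(ss = 1, red = 2), seq(0, 50, 1))
  expect_identical(redox_stage(tcI), "reduction")
  # stage II: redox cycle balanced at late time
  tcII <- simulate_redox(rate_constants(k1 = 1e-2, k2 = 0.5, k4 = 2e-3),
                         system_state(ss = 1, red = 10, o2 = 0.02),
                         seq(0, 1000, length.out = 400))
  expect_identical(redox_stage(tcII, tol = 1e-5), "steady_state")
  # stage III: reducing agent exhausted, net reoxidation under way
  tcIII <- simulate_redox(rate_constants(k1 = 5e-2, k2 = 2e-2, k4 = 2e-3),
                          system_state(ss = 1, red = 1.2, o2 = 0.3),
                          seq(0, 150, 1))
  expect_identical(redox_stage(tcIII), "reoxidation")
})
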