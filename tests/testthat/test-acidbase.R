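# Carbonic-buffer equilibrium chemistry.

test_that("closed-compartment equilibria reproduce the reference scenarios", {
  # full fermentation of 5 mM glucose: 10 mM lactic acid neutralized
  s <- solve_equilibrium(strong_acid = 10)
  expect_equal(s$pH, 6.2, tolerance = 0.05 / 6.2)
  expect_lt(abs(s$HCO3 - 14), 0.3)
  expect_lt(abs(s$CO2 - 11.2), 0.3)

  # respiration of all dissolved O2 (0.13 mM CO2 added)
  r <- solve_equilibrium(tic_shift = 0.13)
  expect_lt(abs(r$pH - 7.35), 0.01)
  expect_lt(abs(r$CO2 - 1.33), 0.01)
  # ~4 nM rise in [H+]
  expect_lt(abs((10^-r$pH - 10^-7.4) * 1e9 - 4), 0.5)

  # identity: re-equilibrating an equilibrium state changes nothing
  eq <- solve_equilibrium(strong_acid = 3)
  again <- solve_equilibrium(0, 0, eq)
  expect_equal(again$pH, eq$pH, tolerance = 1e-10)
  expect_equal(again$CO2, eq$CO2, tolerance = 1e-10)
})

test_that("gas-open compartment clamps CO2 and follows Henderson-Hasselbalch", {
  o <- solve_open_system(10)
  expect_identical(o$CO2, 1.2)
  expect_identical(o$HCO3, 14)
  expect_lt(abs(o$pH - 7.2), 0.05)
  # direct Henderson-Hasselbalch evaluation as independent oracle
  o5 <- solve_open_system(5)
  expect_equal(o5$pH, 6.1 + log10(19 / 1.2), tolerance = 1e-12)
  # no acid: the Henderson-Hasselbalch pH of the arterial pair
  expect_equal(solve_open_system(0)$pH, 6.1 + log10(24 / 1.2),
               tolerance = 1e-12)
})

test_that("henderson_hasselbalch matches its closed form", {
  expect_equal(henderson_hasselbalch(1.2, 24), 7.40, tolerance = 1e-3)
  expect_equal(henderson_hasselbalch(3.7, 3.7), 6.1)
  # cross-check against the flux-balance steady state
  fb <- flux_balance_estimate(5)
  expect_equal(henderson_hasselbalch(fb$CO2, fb$HCO3), fb$pH,
               tolerance = 1e-6)
  expect_error(henderson_hasselbalch(0, 24), "positive")
})

test_that("flux-balance estimator reproduces the steady-state TME composition", {
  fb <- flux_balance_estimate(5)
  expect_lt(abs(fb$pH - 7.0), 0.05)
  expect_lt(abs(fb$HCO3 - 19), 0.3)
  expect_lt(abs(fb$CO2 - 2.45), 0.05)

  # zero gradient: arterial state (up to the tiny re-equilibration of the
  # rounded arterial reference)
  fb0 <- flux_balance_estimate(0)
  expect_equal(fb0$pH, 7.4, tolerance = 2e-3)

  # hand-computed gradient scaling + quadratic oracle at half gradient:
  # lactate gradient 5, HCO3 gradient 2.5, CO2 gradient 5/8
  fb2 <- flux_balance_estimate(2.5)
  expect_equal(fb2$HCO3, 21.5, tolerance = 1e-3)
  ref <- solve_equilibrium(tic_shift = 0, strong_acid = 0,
                           initial = carbonic_state(7.4, 1.2 + 5 / 8, 21.5))
  expect_equal(fb2$pH, ref$pH, tolerance = 1e-9)

  expect_error(flux_balance_estimate(6), "exceeds")
  # the rounded 10:2:1 ratio variant gives the milder estimate
  fb10 <- flux_balance_estimate(5, diffusivity_ratios(d_co2 = 10))
  expect_equal(fb10$CO2, 2.2, tolerance = 0.01)
})

test_that("argument validation catches unphysical inputs", {
  expect_error(solve_equilibrium(-1, 0), "non-negative")
  expect_error(solve_equilibrium(0, 30), "buffer exhaustion")
  expect_error(solve_open_system(24), "buffer exhaustion")
  expect_error(solve_open_system(5, clamped_CO2 = 0), "positive")
  expect_error(carbonic_state(7, -1, 24), "positive")
  expect_error(diffusivity_ratios(d_co2 = 0), "positive")
})

test_that("TIC is conserved and states are equilibrated (property)", {
  set.seed(42)
  for (i in 1:100) {
    a <- runif(1, 0, 20)
    t <- runif(1, 0, 5)
    s <- solve_equilibrium(tic_shift = t, strong_acid = a)
    expect_lt(abs((s$CO2 + s$HCO3) - (25.2 + t)), 1e-10)
    expect_lt(equilibrium_residual(s), 1e-6)
  }
})

test_that("quadratic solution matches a brute-force bisection on [H+]", {
  set.seed(7)
  K <- 10^-6.1
  for (i in 1:100) {
    a <- runif(1, 0, 20) * 1e-3   # M
    t <- runif(1, 0, 5) * 1e-3
    H0 <- 10^-7.4; B0 <- 0.024 - a; C0 <- 0.0012 + a + t
    f <- function(H) H * (B0 + (H - H0)) - K * (C0 - (H - H0))
    lo <- 1e-9; hi <- 1e-3
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    s <- solve_equilibrium(tic_shift = t * 1e3, strong_acid = a * 1e3)
    expect_lt(abs(10^-s$pH - (lo + hi) / 2), 1e-9)
  }
})

test_that("equilibration is path-independent", {
  one <- solve_equilibrium(strong_acid = 8)
  two <- solve_equilibrium(strong_acid = 4,
                           initial = solve_equilibrium(strong_acid = 4))
  expect_equal(one$pH, two$pH, tolerance = 1e-9)
  expect_equal(one$CO2, two$CO2, tolerance = 1e-9)
})

test_that("davenport trajectories are monotone and hit the solver endpoints", {
  cf <- davenport_trajectory(compartment_scenario("fermentation"), 21)
  expect_equal(nrow(cf), 21)
  expect_true(all(diff(cf$pH) < 0))
  expect_equal(cf$pH[21], solve_equilibrium(strong_acid = 10)$pH)
  expect_true(all(abs(cf$TIC_mM - 25.2) < 1e-9))  # closed: TIC constant

  of <- davenport_trajectory(
    compartment_scenario("fermentation", gas_open = TRUE), 21)
  expect_true(all(diff(of$pH) < 0))
  expect_equal(of$pH[21], solve_open_system(10)$pH)
  expect_true(all(of$CO2_mM == 1.2))              # clamped

  cr <- davenport_trajectory(compartment_scenario("respiration"), 11)
  expect_true(all(diff(cr$pH) < 0))
  expect_equal(cr$CO2_mM[11], solve_equilibrium(tic_shift = 0.13)$CO2)

  orsp <- davenport_trajectory(
    compartment_scenario("respiration", gas_open = TRUE), 11)
  expect_true(all(orsp$pH == orsp$pH[1]))         # CO2 escapes: no change

  # zero substrate: constant trajectory
  z <- davenport_trajectory(
    compartment_scenario("fermentation", glucose0 = 0), 5)
  expect_true(all(abs(z$pH - z$pH[1]) < 1e-12))
  expect_error(davenport_trajectory(compartment_scenario("fermentation"), 1),
               "n_steps")
})
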