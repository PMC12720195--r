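# Local rate laws and membrane fluxes.

test_that("fermentative rate law has the stated saturation and inhibition", {
  p <- metabolic_params(J_ferm_max = 1)
  # half-saturation in glucose as the acid inhibition is relieved
  expect_equal(j_ferm(p$K_glucose, 1e-12, p), 0.5, tolerance = 1e-6)
  # half-inhibition at H_i = K_an (pK 7.1), any Hill exponent
  expect_equal(j_ferm(1e9, 10^-7.1, p), 0.5, tolerance = 1e-6)
  # independent scalar evaluation at (2 mM, pH 7.4) with h = 2.25
  h <- 2.25
  expected <- 1 * (2 / 3) * (10^-7.1)^h / ((10^-7.4)^h + (10^-7.1)^h)
  expect_equal(j_ferm(2, 10^-7.4, p), expected, tolerance = 1e-12)
  # first-order variant recoverable through hill_an
  p1 <- metabolic_params(J_ferm_max = 1, hill_an = 1)
  expect_equal(j_ferm(2, 10^-7.4, p1),
               (2 / 3) * 10^-7.1 / (10^-7.4 + 10^-7.1), tolerance = 1e-12)
  # bounded and monotone
  g <- seq(0, 20, by = 0.5)
  expect_true(all(diff(j_ferm(g, 10^-7.2, p)) > 0))
  H <- 10^-seq(7.8, 6.2, by = -0.1)
  expect_true(all(diff(j_ferm(5, H, p)) < 0))
  expect_true(all(j_ferm(g, 10^-7.2, p) <= 1))
  expect_error(j_ferm(-1, 1e-7, p), ">= 0")
})

test_that("respiratory rate law has the stated half-saturations", {
  p <- metabolic_params(J_resp_max = 2)
  expect_equal(j_resp(p$K_glucose, 1, p), 1, tolerance = 1e-6)
  expect_equal(j_resp(1e9, 1e-6, p), 1, tolerance = 1e-6)   # 1 uM O2
  expected <- 2 * (1 / 2) * (1e-7 / (1e-7 + 1e-6))
  expect_equal(j_resp(1, 1e-7, p), expected, tolerance = 1e-12)
  o <- seq(0, 1e-5, length.out = 30)
  expect_true(all(diff(j_resp(5, o, p)) > 0))
  expect_error(j_resp(1, -1, p), ">= 0")
})

test_that("NHE flux is sigmoidal with half-max at K_NHE", {
  p <- nhe_params()
  expect_equal(j_nhe(10^-6.7, p), 5, tolerance = 1e-9)
  expect_equal(j_nhe(0, p), 0)
  expect_equal(j_nhe(1e-7, p), 10 * 1e-14 / (1e-14 + 10^(-2 * 6.7)),
               tolerance = 1e-12)
  H <- 10^-seq(8, 6, by = -0.1)
  expect_true(all(diff(j_nhe(H, p)) > 0))
  expect_true(all(j_nhe(H, p) < p$J_NHE_max))
})

test_that("CO2 hydration flux vanishes at equilibrium and restores it", {
  b <- buffer_kinetics()
  eq <- solve_equilibrium(strong_acid = 6)
  expect_equal(co2_hydration_net(eq$CO2, eq$HCO3, 10^-eq$pH, b), 0,
               tolerance = 1e-6)
  # doubled CO2: forward (positive) flux; doubled HCO3: backward
  expect_gt(co2_hydration_net(2 * eq$CO2, eq$HCO3, 10^-eq$pH, b), 0)
  expect_lt(co2_hydration_net(eq$CO2, 2 * eq$HCO3, 10^-eq$pH, b), 0)
  # catalysis scales the magnitude
  expect_equal(co2_hydration_net(2 * eq$CO2, eq$HCO3, 10^-eq$pH, b, TRUE) /
               co2_hydration_net(2 * eq$CO2, eq$HCO3, 10^-eq$pH, b, FALSE),
               b$ca_acceleration, tolerance = 1e-9)

  # integrating the flux alone from a perturbed closed pool reaches the
  # quadratic equilibrium (acidbase oracle); uncatalyzed kinetics keep the
  # explicit integration stable, equilibrium is the same
  C <- 11.2; B <- 14; H <- 10^-7.4   # post-titration, pre-equilibration
  dt <- 1e-4
  for (i in 1:20000) {
    phi <- co2_hydration_net(C, B, H, b, catalyzed = FALSE)
    C <- C - phi * dt
    B <- B + phi * dt
    H <- H + phi * dt * 1e-3
  }
  ref <- solve_equilibrium(strong_acid = 10)
  expect_equal(-log10(H), ref$pH, tolerance = 1e-4)
  expect_equal(C, ref$CO2, tolerance = 1e-3)
})

test_that("transmembrane fluxes conserve and respect stoichiometry", {
  tp <- transport_params()
  # equal concentrations on both sides: zero flux for every solute
  st <- list(glucose_i = 3, glucose_e = 3, lactate_i = 2, lactate_e = 2,
             H_i = 1e-7, H_e = 1e-7, CO2_i = 1.5, CO2_e = 1.5,
             O2_i = 0.1, O2_e = 0.1)
  expect_true(all(abs(transmembrane_fluxes(st, tp)) < 1e-12))

  # H+ is co-transported equimolar with lactate
  st2 <- within(st, { lactate_i <- 6; H_i <- 2e-7 })
  fl <- transmembrane_fluxes(st2, tp)
  expect_lt(fl[["lactate"]], 0)           # efflux
  expect_identical(fl[["lactate"]], fl[["H"]])

  # permeability limit: integrating the CO2 flux equilibrates interior
  ci <- 0.2
  for (i in 1:2000) {
    f <- transmembrane_fluxes(within(st, CO2_i <- ci), tp)
    ci <- ci + f[["CO2"]] * 1e-5
  }
  expect_equal(ci, st$CO2_e, tolerance = 1e-6)

  # at the fermentative spheroid steady state, the membrane carries lactate
  # out at the fermentative rate and glucose in at half that rate
  sol <- cached("sph_ferm_coarse", coarse_spheroid(J_ferm = 10))
  f <- sol$fields[20, ]
  jf <- j_ferm(f$glucose_i, f$H_i_nM * 1e-9, sol$metabolism)
  fl <- transmembrane_fluxes(list(
    glucose_i = f$glucose_i, glucose_e = f$glucose_e,
    lactate_i = f$lactate_i, lactate_e = f$lactate_e,
    H_i = f$H_i_nM * 1e-9, H_e = f$H_e_nM * 1e-9), sol$transport)
  expect_equal(fl[["lactate"]], -jf, tolerance = 1e-4)
  expect_equal(fl[["glucose"]], jf / 2, tolerance = 1e-4)
})

test_that("the regulation pair balances at the pHi set-point", {
  p <- nhe_params()
  # extrusion and acid loading cross exactly at the set-point
  H_set <- 10^-p$pHi_setpoint
  expect_equal(j_nhe(H_set, p), j_ae(H_set, p), tolerance = 1e-12)
  # corrective on both sides: net extrusion below the set-point, net
  # loading above it
  expect_gt(j_nhe(10^-6.9, p), j_ae(10^-6.9, p))
  expect_lt(j_nhe(10^-7.5, p), j_ae(10^-7.5, p))

  # without metabolic acid, a regulated cell settles at the set-point and
  # the balanced pair leaves pHe arterial
  sol <- cached("sph_nhe_only",
                solve_spheroid(spheroid_geometry(radius = 200, n_shells = 20),
                               metabolic_params(), nhe = nhe_params()))
  expect_true(sol$converged)
  expect_true(all(abs(sol$fields$pH_i - 7.2) < 0.02))
  expect_true(all(abs(sol$fields$pH_e - 7.4) < 0.02))
})
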