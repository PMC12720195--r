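# Spheroid diffusion-reaction model: structure, conservation, convergence.

test_that("zero metabolism gives uniform arterial fields", {
  sol <- cached("sph_zero", coarse_spheroid(n_shells = 20))
  expect_true(sol$converged)
  f <- sol$fields
  expect_true(all(abs(f$pH_e - 7.4) < 0.01))
  expect_true(all(abs(f$O2 - 0.13) < 1e-6))
  expect_true(all(abs(f$glucose_e - 5) < 1e-6))
  expect_true(all(abs(f$HCO3_e - 24) < 0.05))
  expect_true(is.na(anoxic_depth(sol)))
})

test_that("fermentative spheroid erects the expected radial structure", {
  sol <- cached("sph_ferm_coarse", coarse_spheroid(J_ferm = 10))
  expect_true(sol$converged)
  f <- sol$fields
  # concentrations are physical and profiles monotone toward the core
  expect_true(all(f[, !(names(f) %in% c("r_um", "pH_e", "pH_i"))] >= 0))
  expect_true(all(diff(f$pH_e) > 0))          # pHe rises toward the surface
  expect_true(all(diff(f$glucose_e) > 0))
  expect_true(all(diff(f$lactate_e) < 0))
  # surface extracellular values approach the boundary composition
  n <- nrow(f)
  expect_lt(abs(f$glucose_e[n] - 5), 0.2)
  expect_lt(abs(f$HCO3_e[n] - 24), 0.3)
  # HCO3- depletion : CO2 accumulation tracks the effective diffusivity
  # ratio (10:2 -> 5) wherever the depletion is appreciable
  dep <- 24 - f$HCO3_e
  ratio <- dep[dep > 0.5] / (f$CO2[dep > 0.5] - 1.2)
  expect_true(all(abs(ratio - 5) < 0.5))
  # no oxygen is consumed
  expect_true(all(abs(f$O2 - 0.13) < 1e-6))
})

test_that("steady-state surface influx balances integrated consumption", {
  for (key in c("sph_ferm_coarse", "sph_resp_coarse")) {
    sol <- cached(key, coarse_spheroid(
      J_ferm = if (key == "sph_ferm_coarse") 10 else 0,
      J_resp = if (key == "sph_resp_coarse") 0.67 else 0))
    fb <- tmeacid:::spheroid_flux_balance(sol)
    for (q in c("glucose", "O2", "lactate")) {
      row <- fb[fb$quantity == q, ]
      if (abs(row$surface_influx) > 1) # skip identically-zero fluxes
        expect_lt(abs(row$surface_influx - row$net_consumption) /
                    abs(row$surface_influx), 0.01)
    }
    # total carbon: net surface flux is zero up to 1% of the glucose carbon
    carbon <- fb[fb$quantity == "carbon", ]
    glc <- fb[fb$quantity == "glucose", ]
    expect_lt(abs(carbon$surface_influx) / (6 * abs(glc$surface_influx)),
              0.01)
  }
})

test_that("respiratory spheroid is anoxia-limited", {
  sol <- cached("sph_resp_coarse", coarse_spheroid(J_resp = 0.67))
  expect_true(sol$converged)
  f <- sol$fields
  d <- anoxic_depth(sol)
  expect_false(is.na(d))
  expect_gt(d, 50)
  expect_lt(d, 400)
  # CO2 plateaus inside the anoxic core: total rise ~ boundary O2 drop
  expect_lt(abs((f$CO2[1] - 1.2) - 0.13), 0.02)
  # HCO3- is not depleted by respiration
  expect_true(all(f$HCO3_e >= 24 - 0.05))
  # modest acidification
  expect_lt(core_values(sol)[["pH_e"]], 7.4)
  expect_gt(core_values(sol)[["pH_e"]], 7.3)
})

test_that("mixed phenotype lies between the pure phenotypes", {
  ferm <- cached("sph_ferm_coarse", coarse_spheroid(J_ferm = 10))
  resp <- cached("sph_resp_coarse", coarse_spheroid(J_resp = 0.67))
  mixed <- cached("sph_mixed_coarse", coarse_spheroid(J_ferm = 5, J_resp = 0.33))
  expect_true(all(mixed$fields$pH_e >= ferm$fields$pH_e - 1e-6))
  expect_true(all(mixed$fields$pH_e <= resp$fields$pH_e + 1e-6))
})

test_that("rate sweep acidifies monotonically and saturates", {
  sw <- cached("sph_rate_sweep",
               rate_sweep(c(0, 1, 10, 30), "ferm",
                          spheroid_geometry(n_shells = 30)))
  expect_true(all(sw$converged))
  expect_lt(abs(sw$pH_e[1] - 7.4), 0.01)      # rate 0: arterial
  expect_true(all(diff(sw$pH_e) <= 1e-8))     # non-increasing with rate
  # glucose-delivery limitation saturates the response near 10 mM/min:
  # tripling the rate beyond it moves core pH far less than reaching it did
  expect_lt(sw$pH_e[3] - sw$pH_e[4], 0.06)
  expect_gt(sw$pH_e[2] - sw$pH_e[3], 3 * (sw$pH_e[3] - sw$pH_e[4]))
})

test_that("radius sweep: small spheroids stay arterial, acidity grows with size", {
  sw <- cached("sph_radius_sweep",
               radius_sweep(c(50, 200, 400), "ferm", n_shells = 24))
  expect_true(all(sw$converged))
  # at 50 um no standing gradients remain; what is left of the acidification
  # is the pericellular carbonic disequilibrium (~0.05 units at full rate)
  expect_lt(abs(sw$pH_e_core[1] - 7.4), 0.07)
  expect_true(all(diff(sw$pH_e_core) < 0))
  # halving the maximal rate shifts the curve up in pH
  sw_half <- radius_sweep(c(200, 400), "ferm", rate = 5, n_shells = 24)
  expect_true(all(sw_half$pH_e_core >
                    sw$pH_e_core[match(c(200, 400), sw$radius_um)]))
})

test_that("grid refinement converges at first order or better", {
  mp <- metabolic_params(J_ferm_max = 5)
  geo <- function(n) spheroid_geometry(radius = 300, n_shells = n)
  p1 <- core_values(solve_spheroid(geo(15), mp))[["pH_e"]]
  p2 <- core_values(solve_spheroid(geo(30), mp))[["pH_e"]]
  p3 <- core_values(solve_spheroid(geo(60), mp))[["pH_e"]]
  # Richardson: successive differences shrink by >= the refinement factor
  expect_lt(abs(p3 - p2), abs(p2 - p1))
  expect_lt(abs(p3 - p2), 0.005)
})

test_that("constant-rate O2 consumption matches the parabolic closed form", {
  # Hill terms effectively disabled: tiny half-saturations make the sink
  # zero-order while O2 remains positive
  R <- 200
  Jr <- 0.1
  mp <- metabolic_params(J_resp_max = Jr, K_glucose = 1e-9, K_O2 = 1e-12)
  sol <- solve_spheroid(spheroid_geometry(radius = R, n_shells = 100), mp)
  f <- sol$fields
  q <- 6 * Jr * 0.75                     # mM/min per tissue volume
  D <- 2500 * 60                         # um^2/min
  analytic <- 0.13 - (q / (6 * D)) * (R^2 - f$r_um^2)
  expect_true(all(analytic > 0))
  expect_lt(max(abs(f$O2 - analytic)) / 0.13, 0.01)
})

test_that("core pH sits at the fast-CA asymptote", {
  base <- cached("sph_ferm_ca1000",
                 solve_spheroid(spheroid_geometry(n_shells = 40),
                                metabolic_params(J_ferm_max = 10)))
  fast <- solve_spheroid(spheroid_geometry(n_shells = 40),
                         metabolic_params(J_ferm_max = 10),
                         buffering = buffer_kinetics(ca_acceleration = 1e4))
  # 10x faster catalysis barely moves the answer: near equilibrium already
  expect_lt(abs(core_values(fast)[["pH_e"]] - core_values(base)[["pH_e"]]),
            0.01)
  # 10x slower catalysis leaves interstitial H+ measurably out of carbonic
  # equilibrium (documented asymmetry; pH shifts acidward by < 0.1)
  slow <- solve_spheroid(spheroid_geometry(n_shells = 40),
                         metabolic_params(J_ferm_max = 10),
                         buffering = buffer_kinetics(ca_acceleration = 100))
  d <- core_values(base)[["pH_e"]] - core_values(slow)[["pH_e"]]
  expect_gt(d, 0)
  expect_lt(d, 0.1)
})
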