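# Carbonic-buffer equilibrium chemistry: the CO2/HCO3- pool is treated as the
# dominant extracellular buffer, equilibrated by carbonic anhydrase, with
# apparent pK 6.1. Concentrations are stored in mM; the equilibrium ratio is
# evaluated in molar, matching the quadratic form K = [H+][HCO3-]/[CO2].

#' Apparent equilibrium constant of the carbonic buffer (molar)
#'
#' @keywords internal
CARBONIC_K <- 10^-6.1

#' A pH / CO2 / bicarbonate state of the carbonic buffer
#'
#' Bundles a pH value with the CO2 and HCO3- concentrations (mM) that
#' produce it. States returned by the equilibrium solvers satisfy
#' \eqn{[H^+][HCO_3^-]/[CO_2] = 10^{-6.1}} (concentrations in molar) to a
#' relative residual below 1e-6; see [equilibrium_residual()].
#'
#' @param pH extracellular pH (dimensionless).
#' @param CO2 dissolved CO2 concentration, mM. Must be positive.
#' @param HCO3 bicarbonate concentration, mM. Must be positive.
#' @return An object of class `carbonic_state`: a named list with elements
#'   `pH`, `CO2` and `HCO3`.
#' @examples
#' carbonic_state(7.4, 1.2, 24)
#' @export
carbonic_state <- function(pH, CO2, HCO3) {
  stopifnot(is.numeric(pH), is.numeric(CO2), is.numeric(HCO3),
            length(pH) == 1L, length(CO2) == 1L, length(HCO3) == 1L)
  if (!is.finite(pH) || !is.finite(CO2) || !is.finite(HCO3))
    stop("carbonic_state components must be finite")
  if (CO2 <= 0 || HCO3 <= 0)
    stop("CO2 and HCO3 must be positive (got CO2 = ", CO2,
         " mM, HCO3 = ", HCO3, " mM)")
  structure(list(pH = pH, CO2 = CO2, HCO3 = HCO3), class = "carbonic_state")
}

#' @export
print.carbonic_state <- function(x, ...) {
  cat(sprintf("<carbonic_state> pH %.3f | CO2 %.3f mM | HCO3 %.2f mM | TIC %.2f mM\n",
              x$pH, x$CO2, x$HCO3, x$CO2 + x$HCO3))
  res <- equilibrium_residual(x)
  cat(sprintf("  equilibrium residual: %.2e %s\n", res,
              if (res < 1e-6) "(at equilibrium)" else "(not equilibrated)"))
  invisible(x)
}

#' Arterial reference state: pH 7.4, 24 mM HCO3-, 1.2 mM CO2
#'
#' @return A [carbonic_state()].
#' @export
arterial_state <- function() carbonic_state(7.4, 1.2, 24)

#' Relative departure of a state from carbonic equilibrium
#'
#' @param state a [carbonic_state()].
#' @return `abs(H * HCO3 - K * CO2) / (K * CO2)` with concentrations in molar.
#' @export
equilibrium_residual <- function(state) {
  H <- 10^-state$pH
  B <- state$HCO3 * 1e-3
  C <- state$CO2 * 1e-3
  abs(H * B - CARBONIC_K * C) / (CARBONIC_K * C)
}

#' Henderson-Hasselbalch pH of a CO2/HCO3- pair
#'
#' @param CO2 dissolved CO2, mM (positive).
#' @param HCO3 bicarbonate, mM (positive).
#' @return pH = 6.1 + log10(HCO3/CO2). Vectorized.
#' @examples
#' henderson_hasselbalch(1.2, 24)  # 7.4, the arterial reference
#' @export
henderson_hasselbalch <- function(CO2, HCO3) {
  if (any(!is.finite(CO2)) || any(!is.finite(HCO3)) ||
      any(CO2 <= 0) || any(HCO3 <= 0))
    stop("henderson_hasselbalch requires positive, finite CO2 and HCO3")
  6.1 + log10(HCO3 / CO2)
}

# Re-equilibrate a perturbed (H0, B0, C0) triple (molar) by interconverting
# x mol/L of CO2 into H+ + HCO3- (x may be negative). The physical root of
#   x^2 + (H0 + B0 + K) x + (H0 B0 - K C0) = 0
# is the one keeping all three concentrations positive; because H0 << B0 the
# quadratic is well conditioned, but a bisection fallback on the monotone
# residual in [H+] guards marginal discriminants.
equilibrate_molar <- function(H0, B0, C0) {
  b <- H0 + B0 + CARBONIC_K
  cc <- H0 * B0 - CARBONIC_K * C0
  disc <- b^2 - 4 * cc
  if (disc >= .Machine$double.eps * b^2) {
    # numerically stable form: avoids cancellation when cc is small
    x <- if (cc <= 0) (-b + sqrt(disc)) / 2 else (2 * -cc) / (b + sqrt(disc))
  } else {
    f <- function(H) H * (B0 + (H - H0)) - CARBONIC_K * (C0 - (H - H0))
    x <- stats::uniroot(function(H) f(H), c(1e-12, 1e-2), tol = 1e-15)$root - H0
  }
  H <- H0 + x; B <- B0 + x; C <- C0 - x
  if (H <= 0 || B <= 0 || C <= 0)
    stop("equilibration left the physical domain (buffer exhausted?)")
  list(H = H, B = B, C = C, x = x)
}

#' Closed-compartment carbonic equilibrium after metabolic acid loading
#'
#' Models a hermetically sealed block of tissue (or an unvented culture dish):
#' total inorganic carbon TIC = CO2 + HCO3 can change only through the
#' `tic_shift` term. Lactic acid neutralization (`strong_acid`) converts
#' HCO3- to CO2 one-to-one; respiration adds CO2 directly (`tic_shift`).
#' The pool is then re-equilibrated by solving the carbonic quadratic for the
#' CO2 <-> H+ + HCO3- interconversion.
#'
#' @param tic_shift mM of CO2 added to the pool (respiratory acid load).
#' @param strong_acid mM of strong (lactic) acid neutralized by HCO3-.
#' @param initial starting [carbonic_state()]; defaults to arterial.
#' @return The equilibrated [carbonic_state()]. Its TIC equals the initial
#'   TIC plus `tic_shift` exactly.
#' @examples
#' solve_equilibrium(strong_acid = 10)   # full fermentation of 5 mM glucose
#' solve_equilibrium(tic_shift = 0.13)   # respiration of all dissolved O2
#' @export
solve_equilibrium <- function(tic_shift = 0, strong_acid = 0,
                              initial = arterial_state()) {
  stopifnot(is.numeric(tic_shift), is.numeric(strong_acid))
  if (tic_shift < 0 || strong_acid < 0)
    stop("tic_shift and strong_acid must be non-negative")
  if (strong_acid > initial$HCO3)
    stop("buffer exhaustion: strong_acid (", strong_acid,
         " mM) exceeds available HCO3- (", initial$HCO3,
         " mM); the carbonic buffer cannot neutralize this load")
  H0 <- 10^-initial$pH
  B0 <- (initial$HCO3 - strong_acid) * 1e-3
  C0 <- (initial$CO2 + strong_acid + tic_shift) * 1e-3
  if (B0 <= 0) stop("buffer exhaustion: no HCO3- remains")
  eq <- equilibrate_molar(H0, B0, C0)
  carbonic_state(-log10(eq$H), eq$C * 1e3, eq$B * 1e3)
}

#' Gas-open compartment: CO2 clamped, HCO3- titrated by strong acid
#'
#' A culture dish in an incubator: excess CO2 escapes so dissolved CO2 is
#' clamped at the atmospheric value, while lactic acid depletes HCO3- (and
#' TIC with it). pH follows Henderson-Hasselbalch.
#'
#' @param strong_acid mM lactic acid neutralized (must be < initial HCO3-).
#' @param clamped_CO2 mM CO2 imposed by the gas phase (default: initial CO2).
#' @param initial starting [carbonic_state()].
#' @return A [carbonic_state()] with `CO2 == clamped_CO2` exactly.
#' @examples
#' solve_open_system(10)  # ~pH 7.2: the monolayer-culture acidosis floor
#' @export
solve_open_system <- function(strong_acid, clamped_CO2 = initial$CO2,
                              initial = arterial_state()) {
  stopifnot(is.numeric(strong_acid), is.numeric(clamped_CO2))
  if (strong_acid < 0) stop("strong_acid must be non-negative")
  if (clamped_CO2 <= 0) stop("clamped_CO2 must be positive")
  if (strong_acid >= initial$HCO3)
    stop("buffer exhaustion: strong_acid (", strong_acid,
         " mM) >= available HCO3- (", initial$HCO3, " mM)")
  B <- initial$HCO3 - strong_acid
  carbonic_state(henderson_hasselbalch(clamped_CO2, B), clamped_CO2, B)
}

#' Relative diffusivities of the carbonic-buffer shuttle species
#'
#' Effective (tissue-scale) diffusivities relative to lactate. HCO3- moves
#' twice as fast as lactate; CO2, being smaller and able to traverse the
#' intracellular compartment, moves another 4-fold faster than HCO3-
#' (8-fold over lactate at extracellular volume fraction 0.25). The often
#' quoted round figure of 10:2:1 is available via `d_co2 = 10` and shifts the
#' steady-state CO2 estimate from 2.45 to 2.2 mM.
#'
#' @param d_co2,d_hco3,d_lactate,d_glucose relative diffusivities (all > 0).
#' @return A named list of class `diffusivity_ratios`.
#' @export
diffusivity_ratios <- function(d_co2 = 8, d_hco3 = 2, d_lactate = 1,
                               d_glucose = 1) {
  vals <- c(d_co2 = d_co2, d_hco3 = d_hco3, d_lactate = d_lactate,
            d_glucose = d_glucose)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all diffusivity ratios must be positive")
  structure(as.list(vals), class = "diffusivity_ratios")
}

#' Flux-balance estimate of steady-state TME acid-base composition
#'
#' At steady state, the glucose influx into fermenting tissue is balanced by a
#' 2-fold larger lactate efflux, and the co-produced H+ must leave as an
#' HCO3-/CO2 shuttle: HCO3- flows in, CO2 flows out. Each species' standing
#' gradient is the common molar flux divided by its diffusivity, so the
#' HCO3- depletion and CO2 accumulation are the lactate gradient scaled by
#' `d_lactate/d_hco3` and `d_lactate/d_co2`. The perturbed pool is then
#' re-equilibrated with the carbonic quadratic.
#'
#' @param glucose_gradient blood-to-tissue glucose difference, mM, in
#'   \[0, 5\] (5 mM is complete consumption of arterial glucose).
#' @param ratios a [diffusivity_ratios()].
#' @param arterial the source [carbonic_state()].
#' @return The estimated steady-state [carbonic_state()] of the tissue.
#' @examples
#' flux_balance_estimate(5)   # pH ~7.0, HCO3 ~19 mM, CO2 ~2.45 mM
#' @export
flux_balance_estimate <- function(glucose_gradient,
                                  ratios = diffusivity_ratios(),
                                  arterial = arterial_state()) {
  stopifnot(inherits(ratios, "diffusivity_ratios"))
  if (!is.numeric(glucose_gradient) || glucose_gradient < 0)
    stop("glucose_gradient must be non-negative")
  if (glucose_gradient > 5)
    stop("glucose_gradient (", glucose_gradient,
         " mM) exceeds the 5 mM arterial glucose available")
  lac_grad <- 2 * glucose_gradient * ratios$d_glucose / ratios$d_lactate
  b_grad <- lac_grad * ratios$d_lactate / ratios$d_hco3
  c_grad <- lac_grad * ratios$d_lactate / ratios$d_co2
  if (b_grad >= arterial$HCO3)
    stop("buffer exhaustion: implied HCO3- gradient exceeds arterial HCO3-")
  H0 <- 10^-arterial$pH
  eq <- equilibrate_molar(H0, (arterial$HCO3 - b_grad) * 1e-3,
                          (arterial$CO2 + c_grad) * 1e-3)
  carbonic_state(-log10(eq$H), eq$C * 1e3, eq$B * 1e3)
}

#' Compartment scenario for Davenport-style trajectories
#'
#' @param metabolic_mode `"fermentation"` (5 mM glucose -> 10 mM lactic acid)
#'   or `"respiration"` (CO2 production limited by the 0.13 mM dissolved O2
#'   when closed; unlimited when gas-open).
#' @param gas_open logical; if `TRUE`, CO2 is clamped at its initial value
#'   (incubator atmosphere) and only non-volatile solutes accumulate.
#' @param initial starting [carbonic_state()].
#' @param glucose0 initial glucose, mM (default 5, the arterial value).
#' @param free_o2_0 initial dissolved O2, mM (default 0.13 = 13 kPa at
#'   10 uM/kPa solubility).
#' @param respiratory_quotient moles CO2 produced per mole O2 consumed.
#' @return An object of class `compartment_scenario`.
#' @export
compartment_scenario <- function(metabolic_mode = c("fermentation", "respiration"),
                                 gas_open = FALSE,
                                 initial = arterial_state(),
                                 glucose0 = 5, free_o2_0 = 0.13,
                                 respiratory_quotient = 1) {
  metabolic_mode <- match.arg(metabolic_mode)
  if (glucose0 < 0 || free_o2_0 < 0)
    stop("glucose0 and free_o2_0 must be non-negative")
  structure(list(metabolic_mode = metabolic_mode, gas_open = isTRUE(gas_open),
                 initial = initial, glucose0 = glucose0,
                 free_o2_0 = free_o2_0,
                 respiratory_quotient = respiratory_quotient),
            class = "compartment_scenario")
}

#' Davenport trajectory of a compartment scenario
#'
#' Tracks the CO2/HCO3-/pH state as the available substrate is consumed,
#' parameterized linearly by the fraction consumed. Endpoints coincide with
#' [solve_equilibrium()] (closed) or [solve_open_system()] (gas-open) at full
#' consumption. A gas-open respiring compartment keeps TIC and pH constant:
#' generated CO2 escapes.
#'
#' @param scenario a [compartment_scenario()].
#' @param n_steps number of trajectory points (>= 2), including both ends.
#' @return A data.frame with columns `fraction_consumed`, `pH`, `CO2_mM`,
#'   `HCO3_mM`, `TIC_mM`.
#' @export
davenport_trajectory <- function(scenario, n_steps = 50) {
  stopifnot(inherits(scenario, "compartment_scenario"))
  if (!is.numeric(n_steps) || n_steps < 2) stop("n_steps must be >= 2")
  f <- seq(0, 1, length.out = as.integer(n_steps))
  init <- scenario$initial
  acid_total <- 2 * scenario$glucose0                # mM lactic acid
  ferm <- scenario$metabolic_mode == "fermentation"
  states <- lapply(f, function(fi) {
    if (ferm && !scenario$gas_open) {
      solve_equilibrium(strong_acid = fi * acid_total, initial = init)
    } else if (ferm) {
      solve_open_system(fi * acid_total, init$CO2, init)
    } else if (!scenario$gas_open) {
      # closed respiration: CO2 yield capped by dissolved O2 (RQ x 0.13 mM)
      tic <- fi * min(scenario$free_o2_0 * scenario$respiratory_quotient,
                      6 * scenario$glucose0)
      solve_equilibrium(tic_shift = tic, initial = init)
    } else {
      init  # gas-open respiration: CO2 escapes, nothing changes
    }
  })
  data.frame(fraction_consumed = f,
             pH = vapply(states, `[[`, numeric(1), "pH"),
             CO2_mM = vapply(states, `[[`, numeric(1), "CO2"),
             HCO3_mM = vapply(states, `[[`, numeric(1), "HCO3"),
             TIC_mM = vapply(states, function(s) s$CO2 + s$HCO3, numeric(1)))
}
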