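# Local reaction and membrane-flux terms shared by the spheroid and Krogh
# models. Rates are mM/min; intracellular [H+] is handled in molar.

#' Metabolic rate parameters
#'
#' Fermentation is half-saturated at ~1 mM glucose and inhibited by
#' intracellular acidity with half-maximal pK 7.1 and Hill cooperativity 2.25
#' (pancreatic cancer line panel). Respiration is half-maximal at 1 uM O2.
#' `J_ferm_max` is a maximal lactic-acid production rate (glucose consumed at
#' half that rate); `J_resp_max` is a maximal glucose consumption rate (CO2
#' produced at 6 x rate x RQ, O2 consumed at 6 x rate).
#'
#' @param J_ferm_max maximal fermentative rate, mM lactic acid/min.
#' @param J_resp_max maximal respiratory rate, mM glucose/min.
#' @param K_glucose glucose half-saturation, mM.
#' @param K_an half-maximal H+ for acid inhibition of fermentation, M
#'   (10^-7.1 = pK 7.1).
#' @param hill_an cooperativity of the acid inhibition (the `ferm_hill`
#'   option: set to 1 for the first-order form).
#' @param K_O2 O2 half-saturation of respiration, M.
#' @param atp_yield_ratio respiration-to-fermentation per-glucose ATP yield
#'   (bookkeeping only; not used by the rate laws).
#' @param respiratory_quotient moles CO2 per mole O2.
#' @return A list of class `metabolic_params`.
#' @export
metabolic_params <- function(J_ferm_max = 0, J_resp_max = 0,
                             K_glucose = 1, K_an = 10^-7.1, hill_an = 2.25,
                             K_O2 = 1e-6, atp_yield_ratio = 15,
                             respiratory_quotient = 1) {
  stopifnot(J_ferm_max >= 0, J_resp_max >= 0, K_glucose > 0, K_an > 0,
            hill_an > 0, K_O2 > 0, respiratory_quotient > 0)
  structure(list(J_ferm_max = J_ferm_max, J_resp_max = J_resp_max,
                 K_glucose = K_glucose, K_an = K_an, hill_an = hill_an,
                 K_O2 = K_O2, atp_yield_ratio = atp_yield_ratio,
                 respiratory_quotient = respiratory_quotient),
            class = "metabolic_params")
}

#' pHi-regulation (NHE + anion exchange) parameters
#'
#' The Na+/H+ exchanger extrudes H+ with a sigmoidal dependence on
#' intracellular \[H+\] (Hill coefficient 2), half-maximal at `K_NHE`. On its
#' own the printed flux law has no finite operating point: at steady state a
#' cell's lactate efflux already carries away all fermentative H+, so an
#' unopposed extruder alkalinizes until its flux collapses ("a significant
#' flux by NHE would cause the cytoplasm to alkalinize to infinity"). The
#' set-point therefore arises, as in real cells, from pairing the extruder
#' with an alkaline-activated acid loader (Cl-/HCO3- anion exchange,
#' exporting HCO3-), whose maximal rate is chosen so the two fluxes balance
#' exactly at `pHi_setpoint`: net regulatory acid flux is zero at the
#' set-point, corrective below it, and the pair contributes nothing to
#' steady-state pHe once pHi is settled.
#'
#' @param J_NHE_max maximal extrusion rate, mM/min.
#' @param K_NHE half-maximal intracellular \[H+\], M (default 10^-6.7).
#' @param pHi_setpoint regulated intracellular pH (default 7.2); fixes the
#'   anion-exchange midpoint (`K_AE = 10^-pHi_setpoint`) and amplitude.
#' @return A list of class `nhe_params` (fields include the derived
#'   anion-exchanger constants `K_AE` and `V_AE`).
#' @export
nhe_params <- function(J_NHE_max = 10, K_NHE = 10^-6.7, pHi_setpoint = 7.2) {
  stopifnot(J_NHE_max >= 0, K_NHE > 0)
  H_set <- 10^-pHi_setpoint
  nhe_at_set <- J_NHE_max * H_set^2 / (H_set^2 + K_NHE^2)
  structure(list(J_NHE_max = J_NHE_max, K_NHE = K_NHE, hill = 2,
                 pHi_setpoint = pHi_setpoint,
                 K_AE = H_set, V_AE = 2 * nhe_at_set),
            class = "nhe_params")
}

#' Buffering and CO2-hydration kinetics
#'
#' CO2 + H2O <-> H+ + HCO3- proceeds at an uncatalyzed pseudo-first-order
#' hydration rate `k_hydration`, accelerated `ca_acceleration`-fold by
#' carbonic anhydrase (exofacial isoforms in the interstitium, CAII in the
#' cytoplasm). Since every reported outcome is a steady state near
#' equilibrium, results are insensitive to the absolute rate (see the
#' sensitivity test). Non-carbonic ("intrinsic") buffering is linear in pH:
#' `intrinsic_buffer_capacity` mM of acid shifts pH by one unit.
#'
#' @param k_hydration uncatalyzed CO2 hydration rate, 1/min.
#' @param ca_acceleration fold-acceleration by carbonic anhydrase (>= 1).
#' @param intrinsic_buffer_capacity intracellular non-carbonic buffering,
#'   mM per pH unit.
#' @param extracellular_buffer_capacity small interstitial non-carbonic
#'   buffering (proteins, phosphate), mM per pH unit; keeps the extracellular
#'   H+ pool numerically well-posed and is physically realistic.
#' @return A list of class `buffer_kinetics`.
#' @export
buffer_kinetics <- function(k_hydration = 0.15, ca_acceleration = 1000,
                            intrinsic_buffer_capacity = 25,
                            extracellular_buffer_capacity = 2) {
  stopifnot(k_hydration > 0, ca_acceleration >= 1,
            intrinsic_buffer_capacity > 0, extracellular_buffer_capacity > 0)
  structure(list(k_hydration = k_hydration,
                 ca_acceleration = ca_acceleration,
                 intrinsic_buffer_capacity = intrinsic_buffer_capacity,
                 extracellular_buffer_capacity = extracellular_buffer_capacity),
            class = "buffer_kinetics")
}

#' Membrane-transport parameters
#'
#' Symmetric saturable carriers for glucose (GLUT-like) and H+-lactate
#' (monocarboxylate transporter); maximal rates default high enough that
#' membrane transport is not rate-limiting for the metabolic rates swept in
#' the models (sensitivity-tested).
#'
#' @param V_glut,K_glut glucose carrier V_max (mM/min) and K_m (mM).
#' @param V_mct,K_mct_lac MCT V_max (mM/min) and lactate K_m (mM).
#' @param K_mct_H H+ half-saturation of the MCT, M.
#' @param P_co2,P_o2 effective membrane rate constants for CO2 and O2
#'   (1/min); used only by [transmembrane_fluxes()] — the field solvers pool
#'   gases across compartments (the infinite-permeability limit).
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(V_glut = 200, K_glut = 1,
                             V_mct = 400, K_mct_lac = 2, K_mct_H = 1e-7,
                             P_co2 = 1e4, P_o2 = 1e4) {
  stopifnot(V_glut >= 0, K_glut > 0, V_mct >= 0, K_mct_lac > 0, K_mct_H > 0,
            P_co2 >= 0, P_o2 >= 0)
  structure(list(V_glut = V_glut, K_glut = K_glut, V_mct = V_mct,
                 K_mct_lac = K_mct_lac, K_mct_H = K_mct_H,
                 P_co2 = P_co2, P_o2 = P_o2),
            class = "transport_params")
}

#' Fermentative rate law
#'
#' `J_ferm = J_ferm_max * G/(G + K_glucose) * K_an^h / (H_i^h + K_an^h)`
#' with `h = hill_an` (2.25). Returns mM lactic acid per minute; glucose is
#' consumed at half this rate and H+ co-produced equimolar with lactate.
#'
#' @param glucose_i intracellular glucose, mM (>= 0). Vectorized.
#' @param H_i intracellular \[H+\], M (> 0). Vectorized.
#' @param p a [metabolic_params()].
#' @return mM lactic acid / min.
#' @export
j_ferm <- function(glucose_i, H_i, p) {
  if (any(glucose_i < 0, na.rm = TRUE)) stop("glucose_i must be >= 0")
  if (any(H_i <= 0, na.rm = TRUE)) stop("H_i must be > 0")
  h <- p$hill_an
  p$J_ferm_max * glucose_i / (glucose_i + p$K_glucose) *
    p$K_an^h / (H_i^h + p$K_an^h)
}

#' Respiratory rate law
#'
#' `J_resp = J_resp_max * G/(G + K_glucose) * O2/(O2 + K_O2)`, in mM glucose
#' per minute. O2 is consumed at 6 x the rate and CO2 produced at
#' 6 x rate x RQ.
#'
#' @param glucose_i intracellular glucose, mM (>= 0). Vectorized.
#' @param O2_i local \[O2\], M (>= 0). Vectorized.
#' @param p a [metabolic_params()].
#' @return mM glucose / min.
#' @export
j_resp <- function(glucose_i, O2_i, p) {
  if (any(glucose_i < 0, na.rm = TRUE)) stop("glucose_i must be >= 0")
  if (any(O2_i < 0, na.rm = TRUE)) stop("O2_i must be >= 0")
  p$J_resp_max * glucose_i / (glucose_i + p$K_glucose) *
    O2_i / (O2_i + p$K_O2)
}

#' NHE acid-extrusion rate law
#'
#' `J_NHE = J_NHE_max * H_i^2 / (H_i^2 + K_NHE^2)`: half-maximal at
#' `H_i = K_NHE`, vanishing as the cytoplasm alkalinizes.
#'
#' @param H_i intracellular \[H+\], M (>= 0). Vectorized.
#' @param p an [nhe_params()].
#' @return mM H+ extruded / min.
#' @export
j_nhe <- function(H_i, p) {
  if (any(H_i < 0, na.rm = TRUE)) stop("H_i must be >= 0")
  p$J_NHE_max * H_i^2 / (H_i^2 + p$K_NHE^2)
}

#' Anion-exchanger (acid-loading) rate law of the pHi-regulation pair
#'
#' Alkaline-activated HCO3- export: `V_AE * K_AE^2 / (H_i^2 + K_AE^2)`.
#' With the constants derived in [nhe_params()], this flux equals [j_nhe()]
#' exactly at the pHi set-point, making the set-point the stable operating
#' point of the pair.
#'
#' @param H_i intracellular \[H+\], M (>= 0). Vectorized.
#' @param p an [nhe_params()].
#' @return mM HCO3- exported (acid loaded) / min.
#' @export
j_ae <- function(H_i, p) {
  if (any(H_i < 0, na.rm = TRUE)) stop("H_i must be >= 0")
  p$V_AE * p$K_AE^2 / (H_i^2 + p$K_AE^2)
}

#' Net CO2 hydration flux
#'
#' Net forward flux of CO2 + H2O -> H+ + HCO3-, driving the pool toward the
#' K = 10^-6.1 equilibrium: `k_f * CO2 - (k_f / K) * H * HCO3`, with `k_f`
#' the (optionally CA-accelerated) hydration rate. Exactly zero at
#' equilibrium; positive when CO2 is in excess.
#'
#' @param CO2,HCO3 concentrations, mM. Vectorized.
#' @param H \[H+\], M. Vectorized.
#' @param b a [buffer_kinetics()].
#' @param catalyzed logical: apply the carbonic-anhydrase acceleration?
#' @return net CO2 consumption (= HCO3- and H+ production), mM/min.
#' @export
co2_hydration_net <- function(CO2, HCO3, H, b = buffer_kinetics(),
                              catalyzed = TRUE) {
  if (any(CO2 < 0) || any(HCO3 < 0) || any(H <= 0))
    stop("co2_hydration_net requires non-negative CO2/HCO3 and positive H")
  kf <- b$k_hydration * if (isTRUE(catalyzed)) b$ca_acceleration else 1
  kf * CO2 - (kf / CARBONIC_K) * H * HCO3
}

#' Carrier-mediated transmembrane fluxes at a point
#'
#' Glucose crosses on a symmetric saturable carrier; lactate crosses as
#' H+-lactate on the MCT (equimolar H+ co-transport); CO2 and O2 cross by
#' permeability x concentration difference. Effluxes from the cell appear as
#' influxes to the interstitium scaled by the volume-fraction ratio
#' `(1 - v_e)/v_e` (handled by the field solvers).
#'
#' @param state named list/vector with elements `glucose_i`, `glucose_e`,
#'   `lactate_i`, `lactate_e`, `H_i`, `H_e` (M), and optionally `CO2_i`,
#'   `CO2_e`, `O2_i`, `O2_e` (mM).
#' @param tp a [transport_params()].
#' @return Named numeric vector of net influxes into the cell (mM/min per
#'   cell volume): `glucose`, `lactate` (negative = efflux), `H` (carried by
#'   lactate; equals the lactate flux), and `CO2`, `O2` when provided.
#' @export
transmembrane_fluxes <- function(state, tp = transport_params()) {
  s <- as.list(state)
  sat <- function(x, K) x / (x + K)
  j_glc <- tp$V_glut * (sat(s$glucose_e, tp$K_glut) - sat(s$glucose_i, tp$K_glut))
  j_lac <- tp$V_mct * (sat(s$lactate_e, tp$K_mct_lac) * sat(s$H_e, tp$K_mct_H) -
                       sat(s$lactate_i, tp$K_mct_lac) * sat(s$H_i, tp$K_mct_H))
  out <- c(glucose = j_glc, lactate = j_lac, H = j_lac)
  if (!is.null(s$CO2_i) && !is.null(s$CO2_e))
    out <- c(out, CO2 = tp$P_co2 * (s$CO2_e - s$CO2_i))
  if (!is.null(s$O2_i) && !is.null(s$O2_e))
    out <- c(out, O2 = tp$P_o2 * (s$O2_e - s$O2_i))
  out
}
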