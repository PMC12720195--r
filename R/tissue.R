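# Shared tissue physics for the spheroid and Krogh-cylinder models.
#
# Ten solutes per radial cell, ordered:
#   1 O2   (mM, pooled over both compartments; diffuses through total volume)
#   2 CO2  (mM, pooled; diffuses through total volume)
#   3 Ge   glucose, extracellular (mM, per interstitial volume; diffuses)
#   4 Le   lactate, extracellular (mM; diffuses)
#   5 Be   HCO3-, extracellular (mM; diffuses)
#   6 He   H+, extracellular (nM; no spatial flux — acid moves as CO2/HCO3-)
#   7 Gi   glucose, intracellular (mM; zero spatial flux)
#   8 Li   lactate, intracellular (mM; zero spatial flux)
#   9 Bi   HCO3-, intracellular (mM; zero spatial flux)
#  10 Hi   H+, intracellular (nM; zero spatial flux)
#
# Extracellular concentrations are per interstitial volume: with uniform v_e
# the v_e cancels from the Laplacian but appears in the source terms as
# (1 - v_e)/v_e, which is what makes effective CO2 transport ~4-fold faster
# than HCO3- at v_e = 0.25 (flux per tissue area: D grad C for pooled gases
# vs v_e D grad Ce for interstitial species).

N_SPECIES <- 10L
SPECIES_NAMES <- c("O2", "CO2", "glucose_e", "lactate_e", "HCO3_e", "H_e_nM",
                   "glucose_i", "lactate_i", "HCO3_i", "H_i_nM")
DIFFUSIVE <- 1:5

#' Solute diffusivities
#'
#' @param O2,CO2,HCO3,lactate,glucose diffusivities in um^2/s. Gases diffuse
#'   through the total tissue volume; interstitial species are restricted to
#'   the extracellular space (volume-fraction scaling applied by the solvers,
#'   so the effective tissue-scale mobilities at `v_e = 0.25` stand in the
#'   ratio CO2 : HCO3- : lactate = 10 : 2 : 1 with glucose = lactate and
#'   O2 = CO2). Defaults are anchored at the free-solution lactate value
#'   (1000 um^2/s at 37 C) and chosen to honor these ratios exactly.
#' @return Named numeric vector (um^2/s) of class `solute_diffusivities`.
#' @export
solute_diffusivities <- function(O2 = 2500, CO2 = 2500, HCO3 = 2000,
                                 lactate = 1000, glucose = 1000) {
  v <- c(O2 = O2, CO2 = CO2, HCO3 = HCO3, lactate = lactate, glucose = glucose)
  if (any(v <= 0)) stop("diffusivities must be positive")
  structure(v, class = "solute_diffusivities")
}

#' Arterial boundary composition
#'
#' pH 7.4, 24 mM HCO3-, 1.2 mM CO2, 5 mM glucose, 0 lactate, 0.13 mM free O2
#' (13 kPa at the 10 uM/kPa solubility).
#'
#' @return Named list of boundary concentrations (mM; pH dimensionless).
#' @export
arterial_boundary <- function() {
  list(O2 = 0.13, CO2 = 1.2, glucose = 5, lactate = 0, HCO3 = 24, pH = 7.4)
}

# Reaction (non-diffusive) part of dU/dt for a block of radial cells.
# U: n x 10 matrix in the species order above. Returns n x 10 matrix, with
# mM species in mM/min and H+ rows in nM/min.
tissue_reaction_rates <- function(U, v_e, mp, tp, bk, nhe = NULL) {
  vc <- 1 - v_e
  sat <- function(x, K) x / (x + K)
  O2 <- pmax(U[, 1], 0); CO2 <- pmax(U[, 2], 0)
  Ge <- pmax(U[, 3], 0); Le <- pmax(U[, 4], 0); Be <- pmax(U[, 5], 0)
  Gi <- pmax(U[, 7], 0); Li <- pmax(U[, 8], 0); Bi <- pmax(U[, 9], 0)
  HeM <- pmax(U[, 6], 1e-3) * 1e-9
  HiM <- pmax(U[, 10], 1e-3) * 1e-9

  h <- mp$hill_an
  Jf <- mp$J_ferm_max * sat(Gi, mp$K_glucose) * mp$K_an^h / (HiM^h + mp$K_an^h)
  Jr <- mp$J_resp_max * sat(Gi, mp$K_glucose) * sat(O2, mp$K_O2 * 1e3) # K_O2 M -> mM
  Jglc <- tp$V_glut * (sat(Ge, tp$K_glut) - sat(Gi, tp$K_glut))
  Jmct <- tp$V_mct * (sat(Le, tp$K_mct_lac) * sat(HeM, tp$K_mct_H) -
                      sat(Li, tp$K_mct_lac) * sat(HiM, tp$K_mct_H))
  Jnhe <- if (is.null(nhe)) 0 else nhe$J_NHE_max * HiM^2 / (HiM^2 + nhe$K_NHE^2)
  Jae <- if (is.null(nhe)) 0 else nhe$V_AE * nhe$K_AE^2 / (HiM^2 + nhe$K_AE^2)

  kf <- bk$k_hydration * bk$ca_acceleration
  phi_i <- kf * CO2 - (kf / CARBONIC_K) * HiM * Bi
  phi_e <- kf * CO2 - (kf / CARBONIC_K) * HeM * Be

  RQ <- mp$respiratory_quotient
  dU <- matrix(0, nrow(U), N_SPECIES)
  dU[, 1] <- -vc * 6 * Jr
  dU[, 2] <- vc * 6 * RQ * Jr - vc * phi_i - v_e * phi_e
  dU[, 3] <- -(vc / v_e) * Jglc
  dU[, 4] <- -(vc / v_e) * Jmct
  # the anion exchanger moves HCO3- only; its acid-loading effect reaches
  # the H+ pools through the hydration fluxes that restore the HCO3- pools
  dU[, 5] <- phi_e + (vc / v_e) * Jae
  A_e <- phi_e + (vc / v_e) * (Jnhe - Jmct)
  dU[, 6] <- log(10) * pmax(U[, 6], 1e-3) * A_e / bk$extracellular_buffer_capacity
  dU[, 7] <- Jglc - Jf / 2 - Jr
  dU[, 8] <- Jf + Jmct
  dU[, 9] <- phi_i - Jae
  A_i <- Jf + phi_i + Jmct - Jnhe
  dU[, 10] <- log(10) * pmax(U[, 10], 1e-3) * A_i / bk$intrinsic_buffer_capacity
  dU
}

# Conservative finite-volume radial Laplacian operators.
#
# Spherical: shells [ (j-1)dr, j dr ], j = 1..n; Dirichlet boundary value cb
# imposed at the outer surface via a half-cell flux; symmetry (zero flux) at
# the center. Returns function(c, D, cb) -> dc/dt contribution (D in um^2/min).
radial_operator_sphere <- function(radius, n) {
  dr <- radius / n
  rf <- (1:n) * dr                      # face radii (outer face of shell j)
  Af <- rf^2                            # face areas / 4pi
  V <- diff(c(0, rf^3)) / 3             # shell volumes / 4pi
  function(c, D, cb) {
    flux <- D * Af[-n] * diff(c) / dr                 # interior faces
    flux_out <- D * Af[n] * (cb - c[n]) / (dr / 2)    # Dirichlet surface
    (c(flux, flux_out) - c(0, flux)) / V
  }
}

# Cylindrical annulus [r0, r0 + thickness]: wall (Robin) exchange at the
# inner face against a well-mixed capillary, zero flux at the outer rim.
# Returns list(op = function(c, D, wall_flux), r_mid, V, A_wall) where
# wall_flux is the inward flux per wall area (positive into tissue).
radial_operator_annulus <- function(r0, thickness, n) {
  dr <- thickness / n
  rf <- r0 + (0:n) * dr                 # n + 1 faces, rf[1] = wall
  Af <- rf                              # face areas / (2 pi L)
  V <- diff(rf^2) / 2                   # shell volumes / (2 pi L)
  op <- function(c, D, wall_flux) {
    flux <- D * Af[2:n] * diff(c) / dr  # interior faces (inward positive +r)
    (c(flux, 0) - c(Af[1] * -wall_flux, flux)) / V
  }
  list(op = op, r_mid = r0 + ((1:n) - 0.5) * dr, V = V, A_wall = Af[1],
       dr = dr)
}
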