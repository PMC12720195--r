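# Krogh-cylinder convection-diffusion-reaction model: a perfused capillary
# (radially well-mixed blood, strictly one-way axial advection) surrounded by
# a metabolizing tissue annulus. With no axial diffusion in tissue, columns
# at different axial positions couple only through the blood, so the steady
# state is found by marching axially: at each node the radial tissue column
# is solved to steady state against the local blood composition, and the
# blood is advanced with the wall-exchange fluxes.

#' Krogh cylinder geometry
#'
#' @param length capillary length, mm.
#' @param capillary_radius capillary radius, um.
#' @param tissue_thickness thickness of the tissue annulus, um.
#' @param blood_velocity blood velocity, mm/s (default 1: 2 s transit over
#'   the default 2 mm length).
#' @param n_axial axial nodes (first-order upwind marching).
#' @param n_radial radial finite-volume shells in the tissue annulus.
#' @return List of class `krogh_geometry`.
#' @export
krogh_geometry <- function(length = 2, capillary_radius = 5,
                           tissue_thickness = 250, blood_velocity = 1,
                           n_axial = 200, n_radial = 25) {
  stopifnot(length > 0, capillary_radius > 0, tissue_thickness > 0,
            blood_velocity > 0, n_axial >= 10, n_radial >= 10)
  structure(list(length = length, capillary_radius = capillary_radius,
                 tissue_thickness = tissue_thickness,
                 blood_velocity = blood_velocity,
                 n_axial = as.integer(n_axial),
                 n_radial = as.integer(n_radial)),
            class = "krogh_geometry")
}

#' Blood-compartment parameters
#'
#' Hemoglobin carries a 9 mM O2 reservoir released along a Hill dissociation
#' curve (n = 2.7, P50 = 3.6 kPa = 36 uM free O2 at the 10 uM/kPa
#' solubility). Non-carbonic blood buffering (hemoglobin and plasma protein)
#' is linear in pH. Both stay confined to blood. The wall permeability is
#' deliberately high (equilibration length ~50 um << capillary length) so
#' that radial tissue diffusion, not the wall, is rate-limiting.
#'
#' @param hb_capacity hemoglobin-bound O2 capacity, mM.
#' @param hb_hill Hill coefficient of the dissociation curve.
#' @param hb_p50 free O2 at half-saturation, mM.
#' @param buffer_capacity non-carbonic blood buffering, mM per pH unit.
#' @param wall_permeability capillary wall permeability for paracellular
#'   solutes (glucose, lactate, HCO3-), um/min.
#' @param wall_permeability_gas permeability for O2 and CO2, um/min; much
#'   higher because gases cross the endothelium freely (the wall must not be
#'   rate-limiting for unloading the 9 mM Hb reservoir through a <= 0.13 mM
#'   free-O2 driving difference).
#' @return List of class `blood_params`.
#' @export
blood_params <- function(hb_capacity = 9, hb_hill = 2.7, hb_p50 = 0.036,
                         buffer_capacity = 10, wall_permeability = 3000,
                         wall_permeability_gas = 1e5) {
  stopifnot(hb_capacity >= 0, hb_hill > 0, hb_p50 > 0, buffer_capacity > 0,
            wall_permeability > 0, wall_permeability_gas > 0)
  structure(list(hb_capacity = hb_capacity, hb_hill = hb_hill,
                 hb_p50 = hb_p50, buffer_capacity = buffer_capacity,
                 wall_permeability = wall_permeability,
                 wall_permeability_gas = wall_permeability_gas),
            class = "blood_params")
}

#' Hemoglobin O2 saturation at a free O2 concentration
#'
#' @param free_o2 free O2, mM. Vectorized.
#' @param bp a [blood_params()].
#' @return Fractional saturation in \[0, 1\].
#' @export
hb_saturation <- function(free_o2, bp = blood_params()) {
  x <- pmax(free_o2, 0)^bp$hb_hill
  x / (x + bp$hb_p50^bp$hb_hill)
}

# Invert total blood O2 (free + Hb-bound) -> free O2 (mM).
hb_free_o2 <- function(total, bp) {
  if (total <= 0) return(0)
  f <- function(c) c + bp$hb_capacity * hb_saturation(c, bp) - total
  stats::uniroot(f, c(0, total), tol = 1e-12)$root
}

# Blood acid-base closure. The carbonic pool is at equilibrium and the
# non-carbonic buffer holds a proton load proportional to (7.4 - pH), so the
# "buffer base" BB = HCO3 + beta*(pH - 7.4) is conserved under CO2 addition
# and reduced 1:1 by strong acid. Given TIC and BB, HCO3 solves
#   B + beta*(6.1 + log10(B/(TIC - B)) - 7.4) = BB.
blood_acidbase <- function(TIC, BB, beta) {
  stopifnot(TIC > 0)
  g <- function(B) B + beta * (6.1 + log10(B / (TIC - B)) - 7.4) - BB
  lo <- TIC * 1e-9
  hi <- TIC * (1 - 1e-9)
  B <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  pH <- 6.1 + log10(B / (TIC - B))
  list(pH = pH, HCO3 = B, CO2 = TIC - B)
}

# Arterial blood state in the conserved variables used during transit.
arterial_blood <- function(bp, boundary = arterial_boundary()) {
  list(TIC = boundary$CO2 + boundary$HCO3,
       BB = boundary$HCO3,              # pH 7.4 reference: buffer unloaded
       O2_total = boundary$O2 + bp$hb_capacity * hb_saturation(boundary$O2, bp),
       glucose = boundary$glucose,
       lactate = boundary$lactate)
}

#' Solve the Krogh cylinder model to steady state
#'
#' @param geometry a [krogh_geometry()].
#' @param metabolism a [metabolic_params()].
#' @param blood a [blood_params()].
#' @param transport a [transport_params()].
#' @param buffering a [buffer_kinetics()].
#' @param nhe an [nhe_params()] or `NULL` (no pHi regulation).
#' @param boundary arterial composition, as [arterial_boundary()].
#' @param diffusivities a [solute_diffusivities()].
#' @param v_e tissue extracellular volume fraction.
#' @param tol tissue-column steady-state tolerance.
#' @param keep_tissue logical: keep the full axial x radial tissue fields
#'   (set `FALSE` in sweeps to save memory).
#' @return Object of class `krogh_solution` with elements `blood` (axial
#'   profiles), `tissue` (axial x radial fields), `tissue_mean_pH`
#'   (volume-weighted mean extracellular pH), `venous` (outflow blood
#'   state), `converged`, and the parameter objects.
#' @export
solve_krogh <- function(geometry = krogh_geometry(),
                        metabolism = metabolic_params(),
                        blood = blood_params(),
                        transport = transport_params(),
                        buffering = buffer_kinetics(),
                        nhe = NULL,
                        boundary = arterial_boundary(),
                        diffusivities = solute_diffusivities(),
                        v_e = 0.25, tol = 1e-8, keep_tissue = TRUE) {
  stopifnot(inherits(geometry, "krogh_geometry"))
  g <- geometry
  nr <- g$n_radial
  nz <- g$n_axial
  ann <- radial_operator_annulus(g$capillary_radius, g$tissue_thickness, nr)
  Dmin <- diffusivities * 60
  Dvec <- c(Dmin[["O2"]], Dmin[["CO2"]], Dmin[["glucose"]],
            Dmin[["lactate"]], Dmin[["HCO3"]])
  # per-species wall permeability: gases cross the endothelium freely
  Pw <- c(blood$wall_permeability_gas, blood$wall_permeability_gas,
          rep(blood$wall_permeability, 3))
  # wall flux enters the interstitial compartment for extracellular species:
  # divide by v_e in per-interstitial-volume concentration space
  wall_scale <- c(1, 1, 1 / v_e, 1 / v_e, 1 / v_e)

  make_resid <- function(cb) {
    # cb: blood-side concentrations for species O2, CO2, glucose, lactate, HCO3
    function(u) {
      U <- matrix(u, nrow = nr, byrow = TRUE)
      dU <- tissue_reaction_rates(U, v_e, metabolism, transport, buffering, nhe)
      for (s in DIFFUSIVE) {
        wf <- Pw[s] * (cb[s] - U[1, s]) * wall_scale[s]
        dU[, s] <- dU[, s] + ann$op(U[, s], Dvec[s], wf)
      }
      as.numeric(t(dU))
    }
  }

  bst <- arterial_blood(blood, boundary)
  chem <- blood_acidbase(bst$TIC, bst$BB, blood$buffer_capacity)
  free_o2 <- hb_free_o2(bst$O2_total, blood)

  dz <- g$length * 1000 / nz                 # um
  v_um <- g$blood_velocity * 1000 * 60       # um/min
  kappa <- 2 / (g$capillary_radius * v_um)   # wall-flux -> d(blood)/dz factor

  Uw <- uniform_tissue_state(nr, boundary)   # warm start
  scale <- tissue_scale(nr)
  lower <- tissue_lower(nr)

  blood_rows <- vector("list", nz + 1L)
  tissue_cols <- if (keep_tissue) vector("list", nz) else NULL
  mean_pHe_z <- mean_pHi_z <- mean_O2_z <- numeric(nz)
  converged <- TRUE
  Vw <- ann$V / sum(ann$V)

  record_blood <- function(z) data.frame(
    z_mm = z, pH = chem$pH, CO2 = chem$CO2, HCO3 = chem$HCO3,
    TIC = bst$TIC, buffer_base = bst$BB, glucose = bst$glucose,
    lactate = bst$lactate, O2_free = free_o2, O2_total = bst$O2_total)
  blood_rows[[1L]] <- record_blood(0)

  for (i in seq_len(nz)) {
    cb <- c(free_o2, chem$CO2, bst$glucose, bst$lactate, chem$HCO3)
    out <- newton_ptc(as.numeric(t(Uw)), make_resid(cb),
                      halfband = N_SPECIES, scale = scale, lower = lower,
                      tol = tol, max_iter = 400L)
    converged <- converged && out$converged
    Uw <- matrix(out$u, nrow = nr, byrow = TRUE)
    c1 <- Uw[1, DIFFUSIVE]
    mean_pHe_z[i] <- sum(-log10(Uw[, 6] * 1e-9) * Vw)
    mean_pHi_z[i] <- sum(-log10(Uw[, 10] * 1e-9) * Vw)
    mean_O2_z[i] <- sum(Uw[, 1] * Vw)
    if (keep_tissue) tissue_cols[[i]] <- Uw
    # advance blood over dz in flux form: the wall flux of the solved steady
    # column exactly balances the column's consumption (tissue-limited, so
    # bounded and smooth in z even at near-transparent gas permeability);
    # holding it over the node is first-order upwind.
    W <- Pw * (cb - c1)          # real flux per wall area, positive into tissue
    d <- kappa * dz
    bst$O2_total <- max(bst$O2_total - d * W[1], 0)
    bst$TIC <- max(bst$TIC - d * (W[2] + W[5]), 1e-6)
    bst$BB <- bst$BB - d * W[5]
    bst$glucose <- max(bst$glucose - d * W[3], 0)
    bst$lactate <- max(bst$lactate - d * W[4], 0)
    chem <- blood_acidbase(bst$TIC, bst$BB, blood$buffer_capacity)
    free_o2 <- hb_free_o2(bst$O2_total, blood)
    blood_rows[[i + 1L]] <- record_blood(i * dz / 1000)
  }

  blood_df <- do.call(rbind, blood_rows)
  tissue_df <- NULL
  if (keep_tissue) {
    tissue_df <- do.call(rbind, lapply(seq_len(nz), function(i) {
      d <- as.data.frame(tissue_cols[[i]])
      names(d) <- SPECIES_NAMES
      cbind(z_mm = (i - 0.5) * dz / 1000, r_um = ann$r_mid, d)
    }))
    tissue_df$pH_e <- -log10(tissue_df$H_e_nM * 1e-9)
    tissue_df$pH_i <- -log10(tissue_df$H_i_nM * 1e-9)
  }
  venous <- blood_rows[[nz + 1L]]
  structure(list(
    blood = blood_df, tissue = tissue_df,
    axial_means = data.frame(z_mm = ((seq_len(nz)) - 0.5) * dz / 1000,
                             pH_e = mean_pHe_z, pH_i = mean_pHi_z,
                             O2 = mean_O2_z),
    tissue_mean_pH = mean(mean_pHe_z),
    tissue_mean_pHi = mean(mean_pHi_z),
    venous = venous,
    geometry = g, metabolism = metabolism, blood_params = blood,
    transport = transport, buffering = buffering, nhe = nhe,
    boundary = boundary, diffusivities = diffusivities,
    converged = converged),
    class = "krogh_solution")
}

#' @export
print.krogh_solution <- function(x, ...) {
  v <- x$venous
  cat(sprintf("<krogh_solution> L = %g mm, tissue %g um, %d x %d | %s\n",
              x$geometry$length, x$geometry$tissue_thickness,
              x$geometry$n_axial, x$geometry$n_radial,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  tissue mean pHe: %.3f\n", x$tissue_mean_pH))
  cat(sprintf("  venous: pH %.3f | CO2 %.2f | HCO3 %.1f | lactate %.2f | glucose %.2f | O2tot %.2f mM\n",
              v$pH, v$CO2, v$HCO3, v$lactate, v$glucose, v$O2_total))
  invisible(x)
}

#' Sweep maximal metabolic rate in the Krogh cylinder
#'
#' @param max_rates vector of J_max values, mM/min.
#' @param phenotype `"ferm"` or `"resp"`.
#' @param geometry a [krogh_geometry()].
#' @param ... passed to [solve_krogh()].
#' @return data.frame: `rate`, `tissue_pH` (volume-averaged pHe), venous
#'   `pH`, `CO2`, `HCO3`, `lactate`, `glucose`, `converged`.
#' @export
krogh_rate_sweep <- function(max_rates, phenotype = c("ferm", "resp"),
                             geometry = krogh_geometry(), ...) {
  phenotype <- match.arg(phenotype)
  rows <- lapply(max_rates, function(rate) {
    mp <- if (phenotype == "ferm") metabolic_params(J_ferm_max = rate)
          else metabolic_params(J_resp_max = rate)
    sol <- solve_krogh(geometry, mp, keep_tissue = FALSE, ...)
    v <- sol$venous
    data.frame(rate = rate, tissue_pH = sol$tissue_mean_pH, pH = v$pH,
               CO2 = v$CO2, HCO3 = v$HCO3, lactate = v$lactate,
               glucose = v$glucose, converged = sol$converged)
  })
  do.call(rbind, rows)
}

#' Sweep Krogh cylinder outer radius or length
#'
#' Radius sweep: outer radii at fixed length 2 mm (tissue thickness =
#' radius - capillary radius). Length sweep: lengths at fixed outer radius
#' 250 um. Blood velocity is held constant.
#'
#' @param values radii (um) or lengths (mm).
#' @param axis `"radius"` or `"length"`.
#' @param phenotype `"ferm"` or `"resp"`.
#' @param rate maximal rate; defaults to 1 (ferm) or 0.067 (resp) mM/min.
#' @param n_axial,n_radial grid resolution per solve.
#' @param ... passed to [solve_krogh()].
#' @return data.frame: `value`, `tissue_pH`, venous `pH`, `converged`.
#' @export
krogh_geometry_sweep <- function(values, axis = c("radius", "length"),
                                 phenotype = c("ferm", "resp"), rate = NULL,
                                 n_axial = 100, n_radial = 20, ...) {
  axis <- match.arg(axis)
  phenotype <- match.arg(phenotype)
  if (is.null(rate)) rate <- if (phenotype == "ferm") 1 else 0.067
  mp <- if (phenotype == "ferm") metabolic_params(J_ferm_max = rate)
        else metabolic_params(J_resp_max = rate)
  rows <- lapply(values, function(val) {
    geo <- if (axis == "radius") {
      krogh_geometry(length = 2, tissue_thickness = max(val - 5, 5),
                     n_axial = n_axial, n_radial = n_radial)
    } else {
      krogh_geometry(length = val, tissue_thickness = 245,
                     n_axial = max(20L, round(n_axial * val / 2)),
                     n_radial = n_radial)
    }
    sol <- solve_krogh(geo, mp, keep_tissue = FALSE, ...)
    data.frame(value = val, tissue_pH = sol$tissue_mean_pH,
               pH = sol$venous$pH, converged = sol$converged)
  })
  do.call(rbind, rows)
}

#' Paired pHe/pHi samples across a model domain
#'
#' For spheroids: one sample per radial shell (surface to core). For Krogh
#' cylinders: one volume-weighted radial average per axial position
#' (arterial to venous end); the trajectory typically reverses past its apex
#' as glucose depletion lets downstream tissue recover.
#'
#' @param solution a `spheroid_solution` or `krogh_solution`.
#' @return data.frame with `position` (um depth or mm axial), `pH_e`, `pH_i`.
#' @export
phi_phe_trajectory <- function(solution) {
  if (inherits(solution, "spheroid_solution")) {
    f <- solution$fields[order(-solution$fields$r_um), ]
    data.frame(position = solution$geometry$radius - f$r_um,
               pH_e = f$pH_e, pH_i = f$pH_i, row.names = NULL)
  } else if (inherits(solution, "krogh_solution")) {
    data.frame(position = solution$axial_means$z_mm,
               pH_e = solution$axial_means$pH_e,
               pH_i = solution$axial_means$pH_i, row.names = NULL)
  } else stop("unsupported solution class")
}

#' Paired O2/pHe samples across a model domain
#'
#' Fermentative phenotypes trace a vertical line (acidification without O2
#' consumption); respiratory phenotypes couple the two.
#'
#' @param solution a `spheroid_solution` or `krogh_solution`.
#' @return data.frame with `position`, `O2` (mM), `pH_e`.
#' @export
o2_ph_trajectory <- function(solution) {
  if (inherits(solution, "spheroid_solution")) {
    f <- solution$fields[order(-solution$fields$r_um), ]
    data.frame(position = solution$geometry$radius - f$r_um,
               O2 = f$O2, pH_e = f$pH_e, row.names = NULL)
  } else if (inherits(solution, "krogh_solution")) {
    data.frame(position = solution$axial_means$z_mm,
               O2 = solution$axial_means$O2,
               pH_e = solution$axial_means$pH_e, row.names = NULL)
  } else stop("unsupported solution class")
}
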