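# Steady-state diffusion-reaction model of a multicellular spheroid bathed in
# the equivalent of well-stirred arterial blood: radially symmetric sphere,
# finite-volume shells, steady state by pseudo-transient Newton continuation.

#' Spheroid geometry
#'
#' @param radius spheroid radius, um.
#' @param v_e extracellular volume fraction (0 < v_e < 1).
#' @param n_shells number of radial finite-volume shells (>= 10).
#' @return List of class `spheroid_geometry`.
#' @export
spheroid_geometry <- function(radius = 500, v_e = 0.25, n_shells = 100) {
  stopifnot(radius > 0, v_e > 0, v_e < 1, n_shells >= 10)
  structure(list(radius = radius, v_e = v_e, n_shells = as.integer(n_shells)),
            class = "spheroid_geometry")
}

# Initial uniform state consistent with the boundary composition.
uniform_tissue_state <- function(n, boundary) {
  H_nM <- 10^-boundary$pH * 1e9
  Bi <- CARBONIC_K * boundary$CO2 * 1e-3 / (10^-boundary$pH) * 1e3
  U <- matrix(rep(c(boundary$O2, boundary$CO2, boundary$glucose,
                    max(boundary$lactate, 1e-3), boundary$HCO3, H_nM,
                    boundary$glucose, 1e-3, Bi, H_nM), each = n),
              nrow = n)
  U
}

tissue_scale <- function(n) rep(c(0.1, 1, 1, 1, 10, 100, 1, 1, 10, 100), n)
tissue_lower <- function(n) rep(c(0, 0, 0, 0, 1e-6, 1e-3, 0, 0, 1e-6, 1e-3), n)

#' Solve the spheroid diffusion-reaction model to steady state
#'
#' Ten solutes (O2, CO2, extracellular and intracellular glucose, lactate,
#' HCO3- and H+) on a radial grid. The surface is a constant arterial source
#' for gases and extracellular solutes; intracellular solutes are reflected
#' (zero flux). Steady state is found by pseudo-transient continuation to a
#' residual below `tol` (mM/min; H+ rows in nM/min).
#'
#' @param geometry a [spheroid_geometry()].
#' @param metabolism a [metabolic_params()].
#' @param transport a [transport_params()].
#' @param buffering a [buffer_kinetics()].
#' @param nhe an [nhe_params()] to enable Na+/H+ exchange, or `NULL` (default:
#'   no pHi regulation).
#' @param boundary surface composition, as [arterial_boundary()].
#' @param diffusivities a [solute_diffusivities()] (um^2/s).
#' @param tol steady-state residual tolerance.
#' @param max_iter maximum PTC iterations.
#' @param init optional warm-start state matrix (n_shells x 10).
#' @return Object of class `spheroid_solution`: list with `fields` (data.frame
#'   of radial profiles incl. `pH_e`, `pH_i`), `geometry`, `residual`,
#'   `converged`, `iterations`, and the parameter objects.
#' @examples
#' \donttest{
#' sol <- solve_spheroid(spheroid_geometry(n_shells = 40),
#'                       metabolic_params(J_ferm_max = 10))
#' core_values(sol)["pH_e"]
#' }
#' @export
solve_spheroid <- function(geometry = spheroid_geometry(),
                           metabolism = metabolic_params(),
                           transport = transport_params(),
                           buffering = buffer_kinetics(),
                           nhe = NULL,
                           boundary = arterial_boundary(),
                           diffusivities = solute_diffusivities(),
                           tol = 1e-8, max_iter = 600L, init = NULL) {
  stopifnot(inherits(geometry, "spheroid_geometry"))
  n <- geometry$n_shells
  lap <- radial_operator_sphere(geometry$radius, n)
  Dmin <- diffusivities * 60   # um^2/min
  # diffusive species -> (diffusivity, boundary value)
  Dvec <- c(Dmin[["O2"]], Dmin[["CO2"]], Dmin[["glucose"]],
            Dmin[["lactate"]], Dmin[["HCO3"]])
  bvec <- c(boundary$O2, boundary$CO2, boundary$glucose, boundary$lactate,
            boundary$HCO3)

  resid <- function(u) {
    U <- matrix(u, nrow = n, byrow = TRUE)
    dU <- tissue_reaction_rates(U, geometry$v_e, metabolism, transport,
                                buffering, nhe)
    for (s in DIFFUSIVE)
      dU[, s] <- dU[, s] + lap(U[, s], Dvec[s], bvec[s])
    as.numeric(t(dU))
  }

  U0 <- if (is.null(init)) uniform_tissue_state(n, boundary) else init
  out <- newton_ptc(as.numeric(t(U0)), resid, halfband = N_SPECIES,
                    scale = tissue_scale(n), lower = tissue_lower(n),
                    tol = tol, max_iter = max_iter)
  if (!out$converged)
    warning("spheroid solver did not reach tolerance (residual ",
            format(out$resid, digits = 3), " after ", out$iterations,
            " iterations)")
  U <- matrix(out$u, nrow = n, byrow = TRUE)
  colnames(U) <- SPECIES_NAMES
  dr <- geometry$radius / n
  fields <- data.frame(r_um = ((1:n) - 0.5) * dr, U)
  fields$pH_e <- -log10(fields$H_e_nM * 1e-9)
  fields$pH_i <- -log10(fields$H_i_nM * 1e-9)
  structure(list(fields = fields, state = U, geometry = geometry,
                 metabolism = metabolism, transport = transport,
                 buffering = buffering, nhe = nhe, boundary = boundary,
                 diffusivities = diffusivities,
                 residual = out$resid, converged = out$converged,
                 iterations = out$iterations),
            class = "spheroid_solution")
}

#' @export
print.spheroid_solution <- function(x, ...) {
  cv <- core_values(x)
  cat(sprintf("<spheroid_solution> R = %g um, %d shells | %s (residual %.2e)\n",
              x$geometry$radius, x$geometry$n_shells,
              if (x$converged) "converged" else "NOT converged", x$residual))
  cat(sprintf("  core: pHe %.3f | pHi %.3f | O2 %.4f mM | CO2 %.2f mM | HCO3e %.1f mM\n",
              cv[["pH_e"]], cv[["pH_i"]], cv[["O2"]], cv[["CO2"]],
              cv[["HCO3_e"]]))
  ad <- anoxic_depth(x)
  cat(sprintf("  anoxic depth: %s\n",
              if (is.na(ad)) "none" else paste0(format(ad), " um")))
  invisible(x)
}

#' Solute values at the spheroid core (innermost shell)
#'
#' @param solution a `spheroid_solution`.
#' @return Named numeric vector of core concentrations plus `pH_e`, `pH_i`.
#' @export
core_values <- function(solution) {
  stopifnot(inherits(solution, "spheroid_solution"))
  unlist(solution$fields[1, -1])
}

#' Radial solute profiles in long format
#'
#' @param solution a `spheroid_solution` (or `krogh_solution`, whose tissue
#'   fields are returned per axial position).
#' @return data.frame with columns `r_um`, `solute`, `value` (plus `z_mm` for
#'   Krogh solutions).
#' @export
radial_profiles <- function(solution) {
  if (inherits(solution, "krogh_solution")) {
    f <- solution$tissue
    id <- c("z_mm", "r_um")
  } else {
    f <- solution$fields
    id <- "r_um"
  }
  sol_cols <- setdiff(names(f), id)
  out <- do.call(rbind, lapply(sol_cols, function(s)
    data.frame(f[id], solute = s, value = f[[s]], row.names = NULL)))
  out
}

#' Depth of the anoxic boundary
#'
#' Shallowest depth from the surface at which O2 falls below the anoxia
#' threshold (default 1e-8 M = 1e-5 mM), or `NA` if the spheroid is
#' oxygenated throughout.
#'
#' @param solution a `spheroid_solution`.
#' @param threshold_M anoxia threshold, molar.
#' @return Depth in um, or `NA_real_`.
#' @export
anoxic_depth <- function(solution, threshold_M = 1e-8) {
  stopifnot(inherits(solution, "spheroid_solution"))
  f <- solution$fields
  anox <- f$O2 * 1e-3 < threshold_M
  if (!any(anox)) return(NA_real_)
  # O2 decreases toward the core: boundary at the outermost anoxic shell
  solution$geometry$radius - max(f$r_um[anox])
}

#' Sweep maximal metabolic rate and record core composition
#'
#' @param max_rates vector of J_max values, mM/min.
#' @param phenotype `"ferm"` or `"resp"`: which pathway carries the rate.
#' @param geometry,... passed to [solve_spheroid()].
#' @return data.frame: `rate`, core `pH_e`, `pH_i`, `O2`, `CO2`, `HCO3_e`,
#'   `lactate_e`, `glucose_e`, `anoxic_depth_um`, `converged`.
#' @export
rate_sweep <- function(max_rates, phenotype = c("ferm", "resp"),
                       geometry = spheroid_geometry(), ...) {
  phenotype <- match.arg(phenotype)
  init <- NULL
  rows <- lapply(sort(max_rates), function(rate) {
    mp <- if (phenotype == "ferm") metabolic_params(J_ferm_max = rate)
          else metabolic_params(J_resp_max = rate)
    sol <- solve_spheroid(geometry, mp, init = init, ...)
    init <<- sol$state
    cv <- core_values(sol)
    data.frame(rate = rate, pH_e = cv[["pH_e"]], pH_i = cv[["pH_i"]],
               O2 = cv[["O2"]], CO2 = cv[["CO2"]], HCO3_e = cv[["HCO3_e"]],
               lactate_e = cv[["lactate_e"]], glucose_e = cv[["glucose_e"]],
               anoxic_depth_um = anoxic_depth(sol), converged = sol$converged)
  })
  do.call(rbind, rows)
}

#' Sweep spheroid radius and record core/mean extracellular pH
#'
#' @param radii vector of radii, um.
#' @param phenotype `"ferm"` or `"resp"`.
#' @param rate maximal rate for the chosen pathway, mM/min; defaults to the
#'   near-saturating 10 (ferm) or 0.67 (resp).
#' @param n_shells shells per solve.
#' @param ... passed to [solve_spheroid()].
#' @return data.frame: `radius_um`, `pH_e_core`, `pH_e_mean` (volume-weighted),
#'   `converged`.
#' @export
radius_sweep <- function(radii, phenotype = c("ferm", "resp"), rate = NULL,
                         n_shells = 60, ...) {
  phenotype <- match.arg(phenotype)
  if (is.null(rate)) rate <- if (phenotype == "ferm") 10 else 0.67
  mp <- if (phenotype == "ferm") metabolic_params(J_ferm_max = rate)
        else metabolic_params(J_resp_max = rate)
  rows <- lapply(radii, function(R) {
    sol <- solve_spheroid(spheroid_geometry(radius = R, n_shells = n_shells),
                          mp, ...)
    f <- sol$fields
    w <- diff((seq(0, R, length.out = nrow(f) + 1))^3)
    data.frame(radius_um = R, pH_e_core = f$pH_e[1],
               pH_e_mean = sum(f$pH_e * w) / sum(w), converged = sol$converged)
  })
  do.call(rbind, rows)
}

# Surface influx vs volume-integrated consumption, for conservation tests.
# Returns data.frame(quantity, surface_influx, net_consumption) in
# mM um^3 / min / 4pi units (sphere) for glucose, O2, lactate, carbon.
spheroid_flux_balance <- function(solution) {
  g <- solution$geometry
  n <- g$n_shells
  dr <- g$radius / n
  U <- solution$state
  D <- solution$diffusivities * 60
  b <- solution$boundary
  v_e <- g$v_e
  AR <- g$radius^2
  # surface flux per (area/4pi): pooled species through total volume,
  # extracellular species through v_e of it
  sflux <- function(D1, cb, cn, scale)
    unname(scale * D1 * AR * (cb - cn) / (dr / 2))
  influx <- c(glucose = sflux(D[["glucose"]], b$glucose, U[n, 3], v_e),
              O2 = sflux(D[["O2"]], b$O2, U[n, 1], 1),
              lactate = sflux(D[["lactate"]], b$lactate, U[n, 4], v_e),
              carbon = 6 * sflux(D[["glucose"]], b$glucose, U[n, 3], v_e) +
                3 * sflux(D[["lactate"]], b$lactate, U[n, 4], v_e) +
                sflux(D[["CO2"]], b$CO2, U[n, 2], 1) +
                sflux(D[["HCO3"]], b$HCO3, U[n, 5], v_e))
  dU <- tissue_reaction_rates(U, v_e, solution$metabolism,
                              solution$transport, solution$buffering,
                              solution$nhe)
  V <- diff(c(0, (seq_len(n) * dr)^3)) / 3
  # net consumption per tissue volume (production negative), mM/min
  cons <- function(dcol, scale) -sum(dcol * scale * V)
  consumption <- c(glucose = cons(dU[, 3], v_e) + cons(dU[, 7], 1 - v_e),
                   O2 = cons(dU[, 1], 1),
                   lactate = cons(dU[, 4], v_e) + cons(dU[, 8], 1 - v_e),
                   carbon = 0)
  consumption[["carbon"]] <-
    6 * consumption[["glucose"]] + 3 * consumption[["lactate"]] +
    cons(dU[, 2], 1) + cons(dU[, 5], v_e) + cons(dU[, 9], 1 - v_e)
  data.frame(quantity = names(influx), surface_influx = unname(influx),
             net_consumption = unname(consumption))
}
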