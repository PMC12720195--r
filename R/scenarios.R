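# Figure-level experiment registry: each named scenario reproduces one of the
# headline simulation experiments end-to-end and returns tidy tables plus a
# summary of its headline numbers. Tables are the contract; plotting is left
# to the user (everything is a plain data.frame).

#' Registry of named scenario configurations
#'
#' Covers the compartment Davenport trajectories (fig1a/fig1b, fig5a), the
#' spheroid rate sweep and phenotype profiles (fig3b, fig3c), the Krogh rate
#' sweep and phenotype profiles (fig4b, fig4c), the Davenport summaries
#' (fig5b, fig5c), the geometry sweeps (fig5d, fig5e, fig5f), the pHi/pHe
#' trajectories with and without NHE (fig5g, fig5h, fig5i) and the O2/pH
#' trajectories (fig5j, fig5k, fig5l).
#'
#' @return Named character vector: scenario id -> description.
#' @export
scenario_registry <- function() {
  c(fig1a = "closed vs gas-open fermentation, Davenport trajectory",
    fig1b = "closed vs gas-open respiration, Davenport trajectory",
    fig3b = "spheroid core composition vs maximal fermentative/respiratory rate",
    fig3c = "spheroid radial profiles: fermentative, respiratory, mixed",
    fig4b = "Krogh tissue/venous composition vs maximal metabolic rate",
    fig4c = "Krogh axial profiles: fermentative, respiratory, mixed",
    fig5a = "compartment Davenport diagram (closed and gas-open fermentation)",
    fig5b = "spheroid Davenport trajectories (fermentative, respiratory)",
    fig5c = "Krogh venous Davenport trajectories (fermentative, respiratory)",
    fig5d = "spheroid radius sweep (fermentative, respiratory)",
    fig5e = "Krogh radius sweep at 2 mm length",
    fig5f = "Krogh length sweep at 250 um radius",
    fig5g = "spheroid pHi/pHe trajectory with and without NHE",
    fig5h = "Krogh (50 um radius) pHi/pHe trajectory with and without NHE",
    fig5i = "Krogh (250 um radius) pHi/pHe trajectory with and without NHE",
    fig5j = "spheroid O2 vs pHe trajectory (fermentative, respiratory)",
    fig5k = "Krogh (50 um radius) O2 vs pHe trajectory",
    fig5l = "Krogh (250 um radius) O2 vs pHe trajectory")
}

# resolution -> grid sizes
scenario_grids <- function(resolution) {
  switch(resolution,
         coarse = list(sph = 40L, kz = 60L, kr = 15L, nsweep = 5L),
         full = list(sph = 100L, kz = 200L, kr = 25L, nsweep = 8L),
         stop("resolution must be 'coarse' or 'full'"))
}

#' Run a named scenario
#'
#' @param name a scenario id from [scenario_registry()].
#' @param resolution `"coarse"` (development-grade grids) or `"full"`
#'   (figure-grade grids).
#' @param outdir optional directory; when given, every table is written as
#'   `<name>_<table>.csv` and the summary as `<name>_summary.json`
#'   (requires jsonlite). Outputs are deterministic: rerunning a scenario
#'   with the same configuration gives byte-identical files.
#' @return List of class `scenario_result` with `name`, `description`,
#'   `tables` (named list of data.frames) and `summary` (named list of the
#'   headline numbers of that experiment).
#' @export
run_scenario <- function(name, resolution = c("coarse", "full"),
                         outdir = NULL) {
  resolution <- match.arg(resolution)
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  gr <- scenario_grids(resolution)
  tables <- list()
  summary <- list()

  sph_ferm <- function(n) solve_spheroid(spheroid_geometry(n_shells = n),
                                         metabolic_params(J_ferm_max = 10))
  sph_resp <- function(n) solve_spheroid(spheroid_geometry(n_shells = n),
                                         metabolic_params(J_resp_max = 0.67))
  krogh_run <- function(mp, thickness = 250, nhe = NULL)
    solve_krogh(krogh_geometry(tissue_thickness = thickness,
                               n_axial = gr$kz, n_radial = gr$kr),
                mp, nhe = nhe)

  if (name == "fig1a" || name == "fig5a") {
    closed <- davenport_trajectory(compartment_scenario("fermentation"), 41)
    open <- davenport_trajectory(
      compartment_scenario("fermentation", gas_open = TRUE), 41)
    tables$closed <- closed
    tables$gas_open <- open
    summary$closed_end_pH <- closed$pH[nrow(closed)]
    summary$gas_open_end_pH <- open$pH[nrow(open)]
  } else if (name == "fig1b") {
    closed <- davenport_trajectory(compartment_scenario("respiration"), 41)
    open <- davenport_trajectory(
      compartment_scenario("respiration", gas_open = TRUE), 41)
    tables$closed <- closed
    tables$gas_open <- open
    summary$closed_end_pH <- closed$pH[nrow(closed)]
    summary$closed_end_CO2 <- closed$CO2_mM[nrow(closed)]
  } else if (name == "fig3b") {
    rates <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 30, 100)
    rates_r <- rates / 15
    tables$ferm <- rate_sweep(rates, "ferm",
                              spheroid_geometry(n_shells = gr$sph))
    tables$resp <- rate_sweep(rates_r, "resp",
                              spheroid_geometry(n_shells = gr$sph))
    summary$ferm_plateau_pH <- min(tables$ferm$pH_e)
    summary$resp_plateau_pH <- min(tables$resp$pH_e)
  } else if (name == "fig3c") {
    runs <- list(ferm = metabolic_params(J_ferm_max = 10),
                 resp = metabolic_params(J_resp_max = 0.67),
                 mixed = metabolic_params(J_ferm_max = 5, J_resp_max = 0.33))
    for (ph in names(runs)) {
      sol <- solve_spheroid(spheroid_geometry(n_shells = gr$sph), runs[[ph]])
      tables[[ph]] <- sol$fields
      summary[[paste0(ph, "_core_pHe")]] <- core_values(sol)[["pH_e"]]
      if (ph == "resp") summary$resp_anoxic_depth_um <- anoxic_depth(sol)
    }
  } else if (name == "fig4b") {
    rates <- c(0.01, 0.05, 0.1, 0.5, 1, 5)
    geo <- krogh_geometry(n_axial = gr$kz, n_radial = gr$kr)
    tables$ferm <- krogh_rate_sweep(rates, "ferm", geo)
    tables$resp <- krogh_rate_sweep(rates / 15, "resp", geo)
    summary$ferm_plateau_pH <- min(tables$ferm$tissue_pH)
    summary$resp_plateau_pH <- min(tables$resp$tissue_pH)
  } else if (name == "fig4c") {
    runs <- list(ferm = metabolic_params(J_ferm_max = 1),
                 resp = metabolic_params(J_resp_max = 0.067),
                 mixed = metabolic_params(J_ferm_max = 0.5,
                                          J_resp_max = 0.033))
    for (ph in names(runs)) {
      sol <- krogh_run(runs[[ph]])
      tables[[paste0(ph, "_blood")]] <- sol$blood
      tables[[paste0(ph, "_tissue_means")]] <- sol$axial_means
      summary[[paste0(ph, "_tissue_pH")]] <- sol$tissue_mean_pH
      summary[[paste0(ph, "_venous_pH")]] <- sol$venous$pH
      summary[[paste0(ph, "_venous_lactate")]] <- sol$venous$lactate
      summary[[paste0(ph, "_venous_CO2")]] <- sol$venous$CO2
    }
  } else if (name == "fig5b") {
    for (ph in c("ferm", "resp")) {
      sol <- if (ph == "ferm") sph_ferm(gr$sph) else sph_resp(gr$sph)
      tables[[ph]] <- davenport_points(sol)
    }
  } else if (name == "fig5c") {
    for (th in c(245, 45)) {
      for (ph in c("ferm", "resp")) {
        mp <- if (ph == "ferm") metabolic_params(J_ferm_max = 1)
              else metabolic_params(J_resp_max = 0.067)
        sol <- krogh_run(mp, thickness = th)
        tables[[sprintf("%s_r%d", ph, th + 5)]] <- davenport_points(sol)
      }
    }
  } else if (name == "fig5d") {
    radii <- seq(50, 500, length.out = gr$nsweep)
    tables$ferm <- radius_sweep(radii, "ferm", n_shells = gr$sph %/% 2 * 2)
    tables$resp <- radius_sweep(radii, "resp", n_shells = gr$sph %/% 2 * 2)
  } else if (name == "fig5e") {
    radii <- seq(30, 500, length.out = gr$nsweep)
    for (ph in c("ferm", "resp"))
      tables[[ph]] <- krogh_geometry_sweep(radii, "radius", ph,
                                           n_axial = gr$kz %/% 2,
                                           n_radial = gr$kr)
  } else if (name == "fig5f") {
    lens <- seq(0.25, 5, length.out = gr$nsweep)
    for (ph in c("ferm", "resp"))
      tables[[ph]] <- krogh_geometry_sweep(lens, "length", ph,
                                           n_axial = gr$kz %/% 2,
                                           n_radial = gr$kr)
    nad <- tables$ferm[which.min(tables$ferm$tissue_pH), ]
    summary$ferm_nadir_pH <- nad$tissue_pH
    summary$ferm_nadir_length_mm <- nad$value
  } else if (name %in% c("fig5g", "fig5h", "fig5i")) {
    mk <- function(nhe) {
      if (name == "fig5g") {
        solve_spheroid(spheroid_geometry(radius = 250, n_shells = gr$sph),
                       metabolic_params(J_ferm_max = 10), nhe = nhe)
      } else {
        th <- if (name == "fig5h") 45 else 245
        krogh_run(metabolic_params(J_ferm_max = 1), thickness = th, nhe = nhe)
      }
    }
    no_reg <- mk(NULL)
    reg <- mk(nhe_params())
    tables$without_nhe <- phi_phe_trajectory(no_reg)
    tables$with_nhe <- phi_phe_trajectory(reg)
    summary$max_pHe_drop_without <- 7.4 - min(tables$without_nhe$pH_e)
    summary$max_pHe_drop_with <- 7.4 - min(tables$with_nhe$pH_e)
  } else if (name %in% c("fig5j", "fig5k", "fig5l")) {
    for (ph in c("ferm", "resp")) {
      sol <- if (name == "fig5j") {
        if (ph == "ferm") sph_ferm(gr$sph) else sph_resp(gr$sph)
      } else {
        th <- if (name == "fig5k") 45 else 245
        mp <- if (ph == "ferm") metabolic_params(J_ferm_max = 1)
              else metabolic_params(J_resp_max = 0.067)
        krogh_run(mp, thickness = th)
      }
      tables[[ph]] <- o2_ph_trajectory(sol)
    }
  }

  res <- structure(list(name = name, description = unname(reg[name]),
                        resolution = resolution,
                        tables = tables, summary = summary),
                   class = "scenario_result")
  if (!is.null(outdir)) write_scenario(res, outdir)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %s [%s]\n", x$name, x$description,
              x$resolution))
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  for (nm in names(x$summary))
    cat(sprintf("  %s: %s\n", nm, format(x$summary[[nm]], digits = 4)))
  invisible(x)
}

# Write a scenario result's tables (CSV) and summary (JSON) to a directory.
write_scenario <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$tables))
    utils::write.csv(res$tables[[nm]],
                     file.path(outdir, sprintf("%s_%s.csv", res$name, nm)),
                     row.names = FALSE)
  if (length(res$summary) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(res$summary,
                         file.path(outdir, sprintf("%s_summary.json", res$name)),
                         auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Davenport-diagram points of a model result
#'
#' Extracts (pH, CO2, HCO3) triples for plotting on a Davenport-like diagram
#' ([CO2] against [HCO3-] across iso-pH lines). pH is computed from the
#' CO2/HCO3- pair by Henderson-Hasselbalch, so every emitted triple satisfies
#' the carbonic equilibrium exactly (interstitial H+ in the field models sits
#' within ~1% of equilibrium; the diagram uses the equilibrium pH).
#'
#' For a compartment trajectory (data.frame from [davenport_trajectory()])
#' the points follow consumption; for a `spheroid_solution`, radius (surface
#' to core); for a `krogh_solution`, blood during capillary transit
#' (arterial to venous).
#'
#' @param x a trajectory data.frame, `spheroid_solution`, or `krogh_solution`.
#' @return data.frame with columns `pH`, `CO2_mM`, `HCO3_mM`.
#' @export
davenport_points <- function(x) {
  if (inherits(x, "spheroid_solution")) {
    f <- x$fields[order(-x$fields$r_um), ]
    co2 <- f$CO2; hco3 <- f$HCO3_e
  } else if (inherits(x, "krogh_solution")) {
    co2 <- x$blood$CO2; hco3 <- x$blood$HCO3
  } else if (is.data.frame(x) && all(c("CO2_mM", "HCO3_mM") %in% names(x))) {
    co2 <- x$CO2_mM; hco3 <- x$HCO3_mM
  } else stop("cannot extract Davenport points from this object")
  data.frame(pH = henderson_hasselbalch(co2, hco3),
             CO2_mM = co2, HCO3_mM = hco3)
}
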