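# Expensive steady-state solves are shared across test files through a
# session-level cache keyed by name.
.model_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .model_cache))
    assign(key, force(expr), envir = .model_cache)
  get(key, envir = .model_cache)
}

# Coarse grids used by unit tests (acceptance tests use figure-grade grids).
coarse_spheroid <- function(J_ferm = 0, J_resp = 0, radius = 500,
                            n_shells = 40, ...) {
  solve_spheroid(spheroid_geometry(radius = radius, n_shells = n_shells),
                 metabolic_params(J_ferm_max = J_ferm, J_resp_max = J_resp),
                 ...)
}

coarse_krogh <- function(J_ferm = 0, J_resp = 0, n_axial = 60, n_radial = 12,
                         ...) {
  solve_krogh(krogh_geometry(n_axial = n_axial, n_radial = n_radial),
              metabolic_params(J_ferm_max = J_ferm, J_resp_max = J_resp),
              ...)
}
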