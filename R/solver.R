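# Steady-state solver for the stiff reaction-diffusion systems: damped Newton
# with pseudo-transient continuation (PTC). The state is ordered cell-major
# (all species of shell 1, then shell 2, ...), so the Jacobian is banded with
# half-bandwidth n_block (dense in-shell coupling + same-species neighbor
# coupling through diffusion). The Jacobian is estimated by grouped finite
# differences (2*n_block + 1 residual evaluations) and solved sparsely.

# Grouped finite-difference Jacobian as a sparse matrix.
# fn: residual function (du/dt); u: state; r0: fn(u); halfband: coupling reach.
fd_jacobian <- function(fn, u, r0, halfband, scale) {
  n <- length(u)
  ngroups <- min(2L * halfband + 1L, n)
  eps <- 1e-7
  ii <- jj <- xx <- vector("list", ngroups)
  for (g in seq_len(ngroups)) {
    cols <- seq.int(g, n, by = ngroups)
    du <- numeric(n)
    du[cols] <- eps * pmax(abs(u[cols]), scale[cols])
    r1 <- fn(u + du)
    for (ci in cols) {
      rows <- max(1L, ci - halfband):min(n, ci + halfband)
      ii[[g]] <- c(ii[[g]], rows)
      jj[[g]] <- c(jj[[g]], rep.int(ci, length(rows)))
      xx[[g]] <- c(xx[[g]], (r1[rows] - r0[rows]) / du[ci])
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Pseudo-transient continuation to a steady state of du/dt = fn(u).
#
# u0      initial guess
# fn      residual (time-derivative) function
# halfband Jacobian half-bandwidth (= species per cell for cell-major order)
# scale   per-variable magnitude for FD steps and residual weighting
# lower   elementwise lower bound clamped after each step
# tol     convergence: max(|fn(u)| / pmax(scale_resid,1)) — here plain max|fn|
# Returns list(u, resid, iterations, converged, resid_history).
newton_ptc <- function(u0, fn, halfband, scale,
                       lower = rep(0, length(u0)),
                       tol = 1e-8, dt0 = 1e-4, dt_max = 1e10,
                       max_iter = 400L) {
  u <- pmax(u0, lower)
  r <- fn(u)
  fnorm <- function(r) max(abs(r))
  rn <- fnorm(r)
  best <- rn
  dt <- dt0
  hist <- rn
  n <- length(u)
  iter <- 0L
  # Acceptance is nonmonotone: a physical pseudo-time trajectory may raise
  # the residual transiently, so steps are rejected only on blow-up (or a
  # failed linear solve), and dt grows faster while the residual falls.
  while (rn > tol && iter < max_iter) {
    iter <- iter + 1L
    J <- fd_jacobian(fn, u, r, halfband, scale)
    A <- Matrix::Diagonal(n, 1 / dt) - J
    delta <- tryCatch(as.numeric(Matrix::solve(A, r)),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      dt <- dt / 10
      if (dt < 1e-14) stop("PTC linear solve failed irrecoverably")
      next
    }
    u_try <- pmax(u + delta, lower)
    r_try <- fn(u_try)
    rn_try <- fnorm(r_try)
    if (!is.finite(rn_try) || rn_try > 100 * max(best, tol)) {
      dt <- dt / 4
      if (dt < 1e-14) break
      next
    }
    improved <- rn_try < rn
    u <- u_try; r <- r_try; rn <- rn_try
    best <- min(best, rn)
    dt <- min(dt * if (improved) 2.5 else 1.2, dt_max)
    hist <- c(hist, rn)
  }
  list(u = u, resid = rn, iterations = iter, converged = rn <= tol,
       resid_history = hist)
}
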