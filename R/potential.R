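#' Sodium-tilted double-well potential specification
#'
#' Defines the two-dimensional model free-energy surface used as ground truth
#' by the synthetic-dynamics module: two inverted Gaussian wells (the active E
#' basin and the inactive E* basin), a Gaussian barrier at their midpoint and
#' a harmonic confinement.  When `sodium_state = 1` the coupling term deepens
#' the E well, mimicking the stabilization of the active protease form by a
#' bound Na+ ion.
#'
#' The default parameters place the wells at (+1, 0) (E) and (-1, 0) (E*) and
#' choose depths and coupling such that the equilibrium E population is about
#' 0.38 without sodium and about 0.69 with sodium, i.e. the generator's
#' sodium-off/sodium-on conditions carry the same population shift that the
#' analysis pipeline is meant to detect.
#'
#' @param well_E_center,well_Estar_center numeric 2-vectors, well centers in
#'   reduced length units; must be distinct.
#' @param well_depths numeric 2-vector `c(E, Estar)`, well depths in kT.
#' @param barrier_height Gaussian barrier height at the midpoint, kT; > 0.
#' @param sodium_coupling extra depth (kT) added to the E well when
#'   `sodium_state = 1`; >= 0.
#' @param well_width,barrier_width Gaussian standard deviations (length units).
#' @param confinement force constant of the quadratic confinement centered on
#'   the well midpoint.
#' @param temperature kT scale of the dynamics (default 1).
#' @return An object of class `potential_spec`.
#' @seealso [potential_energy()], [simulate_overdamped()], [reference_solution()]
#' @export
potential_spec <- function(well_E_center = c(1, 0),
                           well_Estar_center = c(-1, 0),
                           well_depths = c(E = 2.5, Estar = 3.53),
                           barrier_height = 1.5,
                           sodium_coupling = 2.35,
                           well_width = 0.5,
                           barrier_width = 0.4,
                           confinement = 0.5,
                           temperature = 1) {
  well_E_center <- as.numeric(well_E_center)
  well_Estar_center <- as.numeric(well_Estar_center)
  stopifnot(length(well_E_center) == 2L, length(well_Estar_center) == 2L,
            length(well_depths) == 2L, is.finite(well_depths))
  if (all(well_E_center == well_Estar_center))
    stop("well centers must be distinct")
  if (!is.finite(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be > 0")
  if (sodium_coupling < 0) stop("sodium_coupling must be >= 0")
  if (well_width <= 0 || barrier_width <= 0)
    stop("well_width and barrier_width must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(
    well_E_center = well_E_center,
    well_Estar_center = well_Estar_center,
    well_depths = c(E = unname(well_depths[1]), Estar = unname(well_depths[2])),
    barrier_height = barrier_height,
    sodium_coupling = sodium_coupling,
    well_width = well_width,
    barrier_width = barrier_width,
    confinement = confinement,
    temperature = temperature
  ), class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("Sodium-tilted double-well potential\n")
  cat(sprintf("  E well:  center (%g, %g), depth %g kT\n",
              x$well_E_center[1], x$well_E_center[2], x$well_depths["E"]))
  cat(sprintf("  E* well: center (%g, %g), depth %g kT\n",
              x$well_Estar_center[1], x$well_Estar_center[2],
              x$well_depths["Estar"]))
  cat(sprintf("  barrier %g kT, sodium coupling %g kT, temperature %g\n",
              x$barrier_height, x$sodium_coupling, x$temperature))
  invisible(x)
}

# Effective well depths for a sodium condition: Na+ binding deepens E.
effective_depths <- function(spec, sodium_state) {
  stopifnot(sodium_state %in% c(0, 1))
  c(E = spec$well_depths[["E"]] + spec$sodium_coupling * sodium_state,
    Estar = spec$well_depths[["Estar"]])
}

# Parameter vector handed to the compiled integrators.
spec_pars <- function(spec, sodium_state) {
  d <- effective_depths(spec, sodium_state)
  c(spec$well_E_center, spec$well_Estar_center, d[["E"]], d[["Estar"]],
    spec$barrier_height, spec$well_width, spec$barrier_width,
    spec$confinement)
}

#' Evaluate the double-well potential energy
#'
#' @param spec a [potential_spec()].
#' @param x numeric 2-vector or n x 2 matrix of positions.
#' @param sodium_state 0 or 1; 1 deepens the E well by `sodium_coupling`.
#' @return numeric vector of energies (kT units).
#' @export
potential_energy <- function(spec, x, sodium_state = 0) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  d <- effective_depths(spec, sodium_state)
  mid <- (spec$well_E_center + spec$well_Estar_center) / 2
  sq <- function(center) (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2
  -d[["E"]] * exp(-sq(spec$well_E_center) / (2 * spec$well_width^2)) -
    d[["Estar"]] * exp(-sq(spec$well_Estar_center) / (2 * spec$well_width^2)) +
    spec$barrier_height * exp(-sq(mid) / (2 * spec$barrier_width^2)) +
    0.5 * spec$confinement * sq(mid)
}

#' Gradient of the double-well potential
#'
#' @inheritParams potential_energy
#' @return n x 2 matrix of gradients.
#' @export
potential_gradient <- function(spec, x, sodium_state = 0) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  d <- effective_depths(spec, sodium_state)
  mid <- (spec$well_E_center + spec$well_Estar_center) / 2
  w2 <- spec$well_width^2; wb2 <- spec$barrier_width^2
  g <- matrix(0, nrow(x), 2)
  for (k in 1:2) {
    dE <- x[, k] - spec$well_E_center[k]
    dS <- x[, k] - spec$well_Estar_center[k]
    dm <- x[, k] - mid[k]
    sqE <- (x[, 1] - spec$well_E_center[1])^2 + (x[, 2] - spec$well_E_center[2])^2
    sqS <- (x[, 1] - spec$well_Estar_center[1])^2 + (x[, 2] - spec$well_Estar_center[2])^2
    sqM <- (x[, 1] - mid[1])^2 + (x[, 2] - mid[2])^2
    g[, k] <- d[["E"]] * exp(-sqE / (2 * w2)) * dE / w2 +
      d[["Estar"]] * exp(-sqS / (2 * w2)) * dS / w2 -
      spec$barrier_height * exp(-sqM / (2 * wb2)) * dm / wb2 +
      spec$confinement * dm
  }
  g
}

#' Euler-Maruyama stability bound for the time step
#'
#' Upper bound on the stiffness (largest curvature) of the potential is
#' `confinement + max(depths)/well_width^2 + barrier_height/barrier_width^2`;
#' the explicit Euler scheme is stable for `dt < 2 / stiffness`.  The default
#' `dt = 1e-3` is two orders of magnitude below the bound for the default
#' parameters.
#'
#' @inheritParams potential_energy
#' @return the maximal stable `dt` (reduced time units).
#' @export
em_stability_dt <- function(spec, sodium_state = 0) {
  d <- effective_depths(spec, sodium_state)
  stiff <- spec$confinement + max(d) / spec$well_width^2 +
    spec$barrier_height / spec$barrier_width^2
  2 / stiff
}

#' Brute-force reference solution of the double-well system
#'
#' Independent oracle for the synthetic dynamics: equilibrium state
#' populations by Boltzmann quadrature on a regular grid (E = half plane
#' nearer the E center), the slowest relaxation time from the discretized
#' master equation (nearest-neighbour hopping generator satisfying detailed
#' balance with respect to the Boltzmann weights; second eigenvalue obtained
#' by deflated inverse iteration on the symmetrized generator), and the mean
#' first passage times between the two basins by sparse linear solves with
#' disk-shaped targets of radius `well_width` around the well centers.
#'
#' @inheritParams potential_energy
#' @param grid_resolution number of grid points per axis (>= 50).
#' @param padding box margin beyond the well centers, length units.
#' @return list with `populations` (named `E`, `Estar`), `relaxation_time`,
#'   `mfpt` (named `E_to_Estar`, `Estar_to_E`), and grid metadata; class
#'   `dw_reference`.
#' @export
reference_solution <- function(spec, sodium_state = 0, grid_resolution = 60,
                               padding = 2.5) {
  if (grid_resolution < 50)
    stop("grid_resolution must be >= 50 so both wells are resolved")
  pops <- function(n) {
    gr <- ref_grid(spec, sodium_state, n, padding)
    c(E = sum(gr$w[gr$isE]) / sum(gr$w),
      Estar = sum(gr$w[!gr$isE]) / sum(gr$w))
  }
  p <- pops(grid_resolution)
  p_half <- pops(max(50, floor(grid_resolution / 2)))
  delta <- max(abs(p - p_half))
  if (delta > 0.01)
    warning(sprintf(
      "populations not converged: halving the grid changes them by %.3g", delta))

  gr <- ref_grid(spec, sodium_state, grid_resolution, padding)
  L <- ref_generator(gr, spec$temperature)
  pi_g <- gr$w / sum(gr$w)

  t_rel <- ref_relaxation_time(L, pi_g)
  inE <- (gr$x - spec$well_E_center[1])^2 + (gr$y - spec$well_E_center[2])^2 <=
    spec$well_width^2
  inS <- (gr$x - spec$well_Estar_center[1])^2 + (gr$y - spec$well_Estar_center[2])^2 <=
    spec$well_width^2
  m_ES <- ref_mfpt(L, pi_g, source = inE, target = inS)
  m_SE <- ref_mfpt(L, pi_g, source = inS, target = inE)

  structure(list(
    populations = p,
    relaxation_time = t_rel,
    mfpt = c(E_to_Estar = m_ES, Estar_to_E = m_SE),
    grid_resolution = grid_resolution,
    convergence_delta = delta,
    sodium_state = sodium_state
  ), class = "dw_reference")
}

#' @export
print.dw_reference <- function(x, ...) {
  cat(sprintf("Double-well reference (grid %d, Na+ %d)\n",
              x$grid_resolution, x$sodium_state))
  cat(sprintf("  populations: E %.4f, E* %.4f\n",
              x$populations["E"], x$populations["Estar"]))
  cat(sprintf("  relaxation time %.3g; mfpt E->E* %.3g, E*->E %.3g\n",
              x$relaxation_time, x$mfpt["E_to_Estar"], x$mfpt["Estar_to_E"]))
  invisible(x)
}

# Square grid over the two wells with Boltzmann weights and E-side mask.
ref_grid <- function(spec, sodium_state, n, padding) {
  lo <- pmin(spec$well_E_center, spec$well_Estar_center) - padding
  hi <- pmax(spec$well_E_center, spec$well_Estar_center) + padding
  ctr <- (lo + hi) / 2
  half <- max(hi - lo) / 2
  gx <- seq(ctr[1] - half, ctr[1] + half, length.out = n)
  gy <- seq(ctr[2] - half, ctr[2] + half, length.out = n)
  h <- gx[2] - gx[1]
  x <- rep(gx, times = n)
  y <- rep(gy, each = n)
  U <- potential_energy(spec, cbind(x, y), sodium_state)
  U <- U - min(U)
  w <- exp(-U / spec$temperature)
  dE2 <- (x - spec$well_E_center[1])^2 + (y - spec$well_E_center[2])^2
  dS2 <- (x - spec$well_Estar_center[1])^2 + (y - spec$well_Estar_center[2])^2
  list(x = x, y = y, n = n, h = h, U = U, w = w, isE = dE2 < dS2)
}

# Nearest-neighbour hopping generator with detailed balance wrt Boltzmann:
# k(i->j) = (kT / h^2) exp(-(U_j - U_i) / (2 kT)) for grid neighbours.
ref_generator <- function(gr, kT) {
  n <- gr$n
  idx <- function(i, j) (j - 1L) * n + i  # column-major over (i = x, j = y)
  i_all <- rep(seq_len(n), times = n)
  j_all <- rep(seq_len(n), each = n)
  from <- integer(0); to <- integer(0)
  # +x and +y neighbour pairs (both directions added below)
  selx <- i_all < n
  from <- c(from, idx(i_all[selx], j_all[selx]))
  to <- c(to, idx(i_all[selx] + 1L, j_all[selx]))
  sely <- j_all < n
  from <- c(from, idx(i_all[sely], j_all[sely]))
  to <- c(to, idx(i_all[sely], j_all[sely] + 1L))
  pref <- kT / gr$h^2
  k_fwd <- pref * exp(-(gr$U[to] - gr$U[from]) / (2 * kT))
  k_bwd <- pref * exp(-(gr$U[from] - gr$U[to]) / (2 * kT))
  N <- n * n
  L <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = c(k_fwd, k_bwd), dims = c(N, N))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  L
}

# Slowest relaxation time 1/lambda_2 by deflated inverse iteration on the
# symmetrized generator S = P^{1/2} L P^{-1/2} (P = diag(pi)).
ref_relaxation_time <- function(L, pi_g, sigma = 1e-9, tol = 1e-10,
                                max_iter = 200) {
  s <- sqrt(pi_g)
  S <- Matrix::Diagonal(x = s) %*% L %*% Matrix::Diagonal(x = 1 / s)
  S <- (S + Matrix::t(S)) / 2
  A <- sigma * Matrix::Diagonal(length(pi_g)) - S  # positive definite
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  v1 <- s / sqrt(sum(s^2))
  x <- pi_g * 0
  x[which.max(pi_g)] <- 1  # arbitrary start with basin overlap
  x <- x - sum(x * v1) * v1
  lam_old <- Inf
  for (it in seq_len(max_iter)) {
    x <- as.numeric(Matrix::solve(ch, x))
    x <- x - sum(x * v1) * v1
    x <- x / sqrt(sum(x^2))
    lam <- -sum(x * as.numeric(S %*% x))  # Rayleigh quotient of -S
    if (is.finite(lam_old) && abs(lam - lam_old) <= tol * max(lam, 1e-30)) break
    lam_old <- lam
  }
  1 / lam
}

# mfpt from basin `source` to basin `target` on the generator: solve
# L_CC m = -1 on the complement of the target, average m over the source
# with Boltzmann weights restricted to the source.
ref_mfpt <- function(L, pi_g, source, target) {
  C <- which(!target)
  m <- numeric(length(pi_g))
  rhs <- rep(-1, length(C))
  m[C] <- as.numeric(Matrix::solve(L[C, C, drop = FALSE], rhs))
  sum(pi_g[source] * m[source]) / sum(pi_g[source])
}
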