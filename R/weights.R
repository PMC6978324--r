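#' MSM frame weights and metastable labels
#'
#' Implements the stationary reweighting of trajectory frames: microstates
#' whose maximal PCCA++ membership does not exceed `cutoff` are excluded
#' (uncertain affiliation); every retained frame observed in microstate `i`
#' receives weight `pi_i / N_i`, where `N_i` is the number of frames observed
#' in `i`, and weights are renormalized over the retained frames.  With this
#' weighting the weighted average of any microstate indicator equals the
#' stationary probability of that microstate (restricted to retained
#' states).
#'
#' @param dtrajs discretized trajectories (list of integer vectors, labels
#'   in the original microstate indexing).
#' @param model an `msm_model` (its `active_set` maps original labels).
#' @param pcca a `pcca_result` for the model.
#' @param cutoff membership cutoff (default 0.90).
#' @param state_names labels for the metastable states (default `"E"`,
#'   `"Estar"` for two states, chosen so that state 1 of the PCCA result is
#'   named first).
#' @return object of class `frame_weights`: `weights` (per frame, 0 for
#'   excluded), `label` (factor with levels `state_names` and `"excluded"`),
#'   `provenance` (trajectory and frame index), `cutoff`.
#' @export
frame_weights <- function(dtrajs, model, pcca, cutoff = 0.90,
                          state_names = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  n_meta <- pcca$n_meta
  if (is.null(state_names))
    state_names <- if (n_meta == 2) c("E", "Estar")
                   else paste0("S", seq_len(n_meta))
  stopifnot(length(state_names) == n_meta)
  max_mem <- apply(pcca$membership, 1, max)
  retained_micro <- max_mem > cutoff      # indices into active set
  if (!any(retained_micro))
    stop(sprintf("membership cutoff %.2f excludes every microstate", cutoff))
  # map original microstate label -> active set position (NA if trimmed)
  n_states <- max(vapply(dtrajs, max, 1L), max(model$active_set))
  to_active <- rep(NA_integer_, n_states)
  to_active[model$active_set] <- seq_along(model$active_set)

  all_states <- unlist(dtrajs, use.names = FALSE)
  prov <- data.frame(
    traj = rep(seq_along(dtrajs), vapply(dtrajs, length, 1L)),
    frame = unlist(lapply(dtrajs, seq_along), use.names = FALSE))
  act <- to_active[all_states]
  keep <- !is.na(act) & retained_micro[ifelse(is.na(act), 1L, act)]
  N_i <- tabulate(act[keep], nbins = length(model$active_set))
  w <- numeric(length(all_states))
  w[keep] <- model$pi[act[keep]] / N_i[act[keep]]
  if (sum(w) == 0) stop("no frames retained after the membership cutoff")
  w <- w / sum(w)
  lab <- rep("excluded", length(all_states))
  lab[keep] <- state_names[pcca$assignment[act[keep]]]
  structure(list(weights = w,
                 label = factor(lab, levels = c(state_names, "excluded")),
                 provenance = prov, cutoff = cutoff,
                 state_names = state_names),
            class = "frame_weights")
}

#' @export
print.frame_weights <- function(x, ...) {
  cat(sprintf("Frame weights: %d frames, cutoff %.2f\n", length(x$weights),
              x$cutoff))
  print(table(x$label))
  invisible(x)
}

#' Freedman-Diaconis histogram breaks on pooled data
#'
#' @param x numeric vector.
#' @param min_bins lower bound on the number of bins.
#' @return vector of break points spanning the data range.
#' @export
fd_breaks <- function(x, min_bins = 10) {
  x <- x[is.finite(x)]
  iqr <- stats::IQR(x)
  h <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else 0
  nb <- if (h > 0) max(min_bins, ceiling(diff(range(x)) / h)) else min_bins
  seq(min(x), max(x), length.out = nb + 1)
}

#' MSM-weighted feature distribution split by metastable state
#'
#' Per-state weighted histograms on shared bins, scaled so that the combined
#' area under all state densities is 1; the integrated probability of each
#' state equals the total frame weight of that state (the coarse stationary
#' probability restricted to retained microstates).
#'
#' @param x numeric feature vector, one value per frame.
#' @param weights a [frame_weights()] object aligned with `x`.
#' @param breaks histogram breaks (default: Freedman-Diaconis on the
#'   retained pooled data).
#' @param name,units feature name and units for labelling.
#' @return object of class `weighted_histogram`: `breaks`, `density`
#'   (bins x states), `state_prob`, `name`, `units`.
#' @export
weighted_distribution <- function(x, weights, breaks = NULL, name = "feature",
                                  units = "") {
  stopifnot(inherits(weights, "frame_weights"),
            length(x) == length(weights$weights))
  keep <- weights$label != "excluded"
  if (is.null(breaks)) breaks <- fd_breaks(x[keep])
  states <- weights$state_names
  nb <- length(breaks) - 1
  widths <- diff(breaks)
  dens <- matrix(0, nb, length(states),
                 dimnames = list(NULL, states))
  state_prob <- stats::setNames(numeric(length(states)), states)
  for (s in states) {
    sel <- weights$label == s
    state_prob[s] <- sum(weights$weights[sel])
    if (!any(sel)) {
      warning(sprintf("metastable state %s holds no retained frames", s))
      next
    }
    bin <- findInterval(x[sel], breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    mass <- vapply(seq_len(nb), function(b) sum(weights$weights[sel][bin == b]),
                   1)
    dens[, s] <- mass / widths
  }
  structure(list(breaks = breaks, density = dens, state_prob = state_prob,
                 name = name, units = units),
            class = "weighted_histogram")
}

#' @export
print.weighted_histogram <- function(x, ...) {
  cat(sprintf("Weighted histogram of %s (%d bins)\n", x$name,
              nrow(x$density)))
  cat("  state probabilities:",
      paste(sprintf("%s %.3f", names(x$state_prob), x$state_prob),
            collapse = ", "), "\n")
  invisible(x)
}

#' Free-energy surface from weighted 2D samples
#'
#' `F(bin) = -kT ln(weighted density)`, shifted so the minimum is 0; bins
#' with no weight are `Inf`.
#'
#' @param Y matrix with exactly 2 columns (e.g. the first two TICs).
#' @param weights numeric frame weights or a [frame_weights()] object.
#' @param kT energy scale (default 1).
#' @param bins number of bins per axis (default 60).
#' @return object of class `fes`: `x_mid`, `y_mid`, `F` (matrix), `kT`.
#' @export
free_energy_surface <- function(Y, weights, kT = 1, bins = 60) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop("free_energy_surface needs exactly 2 columns")
  w <- if (inherits(weights, "frame_weights")) weights$weights else weights
  stopifnot(length(w) == nrow(Y), all(w >= 0))
  bx <- seq(min(Y[, 1]), max(Y[, 1]), length.out = bins + 1)
  by <- seq(min(Y[, 2]), max(Y[, 2]), length.out = bins + 1)
  ix <- findInterval(Y[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(Y[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
  H <- matrix(0, bins, bins)
  for (k in seq_along(w)) H[ix[k], iy[k]] <- H[ix[k], iy[k]] + w[k]
  H <- H / sum(H)
  F <- -kT * log(H)
  F <- F - min(F[is.finite(F)])
  structure(list(x_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 y_mid = (by[-1] + by[-length(by)]) / 2, F = F, kT = kT),
            class = "fes")
}

#' RMSD-to-reference distributions per metastable state
#'
#' Kabsch-aligned RMSD of every frame to each reference conformation over a
#' selection (fit and measurement), summarized per metastable state as
#' weighted histograms plus the min/max range.
#'
#' @param ensemble a `traj_ensemble`.
#' @param references named list of reference frames (n_atoms x 3 matrices),
#'   e.g. `list(E = ..., Estar = ...)`.
#' @param selection atom indices for the RMSD.
#' @param weights a [frame_weights()] aligned with the ensemble frames.
#' @param breaks optional shared histogram breaks.
#' @return list (per reference) of lists with `rmsd` (per frame), `range`
#'   (min/max per state over retained frames) and `histogram`
#'   (a `weighted_histogram`); class `rmsd_reference_summary`.
#' @export
rmsd_to_reference_distribution <- function(ensemble, references, selection,
                                           weights, breaks = NULL) {
  stopifnot(inherits(weights, "frame_weights"),
            n_frames(ensemble) == length(weights$weights))
  out <- lapply(names(references), function(nm) {
    ref <- as.matrix(references[[nm]])
    r <- vapply(seq_len(n_frames(ensemble)), function(i)
      kabsch_rmsd(ensemble$coords[, , i, drop = TRUE], ref, selection)$rmsd,
      1)
    keep <- weights$label != "excluded"
    rng <- t(vapply(weights$state_names, function(s) {
      sel <- weights$label == s
      if (!any(sel)) return(c(min = NA_real_, max = NA_real_))
      c(min = min(r[sel]), max = max(r[sel]))
    }, c(min = 0, max = 0)))
    list(rmsd = r, range = rng,
         histogram = weighted_distribution(r, weights, breaks = breaks,
                                           name = paste0("RMSD_to_", nm),
                                           units = "A"))
  })
  names(out) <- names(references)
  class(out) <- "rmsd_reference_summary"
  out
}

#' Circular (von Mises kernel) dihedral entropy
#'
#' Kernel density of angles on the circle with a von Mises kernel of
#' concentration `kappa` (or `kappa = 1 / bandwidth^2` for a bandwidth in
#' radians, the reciprocal-squared rule), evaluated on a 360-point grid;
#' the differential entropy `-integral p ln p` is taken by the trapezoid
#' rule over the circle in radian measure.  The uniform distribution attains
#' the maximum `ln(2 pi) ~ 1.8379` nats.
#'
#' @param angles_deg numeric vector of angles in degrees (>= 10 values).
#' @param kappa kernel concentration (default 50).
#' @param bandwidth optional kernel bandwidth in radians; overrides `kappa`
#'   via `kappa = 1 / bandwidth^2`.
#' @param weights optional non-negative frame weights.
#' @return entropy in nats.
#' @export
dihedral_entropy <- function(angles_deg, kappa = 50, bandwidth = NULL,
                             weights = NULL) {
  if (length(angles_deg) < 10)
    stop("dihedral_entropy needs at least 10 angles")
  if (!is.null(bandwidth)) {
    stopifnot(bandwidth > 0)
    kappa <- 1 / bandwidth^2
  }
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  stopifnot(length(weights) == length(angles_deg), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  a <- angles_deg * pi / 180
  grid <- seq(-pi, pi, length.out = 361)[-361]
  # scaled von Mises kernel: exp(kappa (cos(d) - 1)) / (2 pi I0(kappa) e^-kappa)
  norm_const <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  p <- vapply(grid, function(g)
    sum(w * exp(kappa * (cos(g - a) - 1))) / norm_const, 1)
  dtheta <- 2 * pi / length(grid)
  p <- p / (sum(p) * dtheta)  # guard quadrature error
  -sum(ifelse(p > 0, p * log(p), 0)) * dtheta
}

#' Closed-form entropy of the von Mises distribution
#'
#' `ln(2 pi I0(kappa)) - kappa I1(kappa) / I0(kappa)` nats; the reference
#' value against which the kernel estimator is validated.
#'
#' @param kappa concentration parameter (>= 0).
#' @return entropy in nats.
#' @export
von_mises_entropy <- function(kappa) {
  i0 <- besselI(kappa, 0, expon.scaled = TRUE)
  i1 <- besselI(kappa, 1, expon.scaled = TRUE)
  log(2 * pi * i0) + kappa - kappa * i1 / i0
}

#' Per-residue psi entropy profile by group
#'
#' @param psi matrix of psi dihedrals (frames x residues, degrees), e.g.
#'   from [psi_dihedrals()].
#' @param groups factor of length `nrow(psi)` (e.g. metastable state labels
#'   from [frame_weights()]); frames labelled `"excluded"` are dropped.
#' @param kappa kernel concentration for [dihedral_entropy()].
#' @return matrix (groups x residues) of entropies in nats; class
#'   `entropy_profile`.
#' @export
psi_entropy_profile <- function(psi, groups, kappa = 50) {
  psi <- as.matrix(psi)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(psi))
  use_levels <- setdiff(levels(groups), "excluded")
  out <- t(vapply(use_levels, function(g) {
    sel <- groups == g
    apply(psi[sel, , drop = FALSE], 2, dihedral_entropy, kappa = kappa)
  }, numeric(ncol(psi))))
  out <- matrix(out, nrow = length(use_levels),
                dimnames = list(use_levels, colnames(psi)))
  class(out) <- c("entropy_profile", "matrix", "array")
  out
}
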