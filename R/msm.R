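#' Transition count matrix at a lag
#'
#' Sliding-window counting within each discretized trajectory (no pairs
#' across trajectory boundaries): every pair `(s_t, s_{t+lag})` contributes
#' one count, so the total equals the sum of `length - lag` over the
#' trajectories used.
#'
#' @param dtrajs integer vector of 1-based microstate labels, or a list of
#'   such vectors.
#' @param lag lag time in frames (>= 1).
#' @param n_states number of microstates (default: maximum observed label).
#' @return integer count matrix with attributes `lag` and `total`.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  dtrajs <- lapply(dtrajs, as.integer)
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 1L))
  usable <- vapply(dtrajs, length, 1L) > lag
  if (!any(usable)) stop("all trajectories are shorter than the lag")
  C <- matrix(0L, n_states, n_states)
  for (d in dtrajs[usable]) {
    n <- length(d)
    from <- d[1:(n - lag)]
    to <- d[(1 + lag):n]
    if (any(from < 1L | from > n_states | to < 1L | to > n_states))
      stop("state label outside 1..n_states")
    tab <- tabulate((from - 1L) * n_states + to, nbins = n_states^2)
    C <- C + matrix(tab, n_states, n_states, byrow = TRUE)
  }
  storage.mode(C) <- "integer"
  attr(C, "lag") <- lag
  attr(C, "total") <- sum(C)
  C
}

#' Largest strongly connected set of a count matrix
#'
#' Vertex set of the largest strongly connected component of the directed
#' graph with an edge `i -> j` wherever `C[i, j] > 0`.  Ties are broken by
#' the component containing the smallest state index.
#'
#' @param C count matrix.
#' @return sorted integer vector of active microstates.
#' @export
largest_connected_set <- function(C) {
  C <- unclass(as.matrix(C))
  if (nrow(C) == 0) stop("empty count matrix")
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {  # tie: component holding the smallest index
    first_member <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
    best <- best[which.min(first_member)]
  }
  sort(which(comp$membership == best))
}

#' Reversible maximum-likelihood Markov state model
#'
#' Trims the counts to the largest strongly connected set, then maximizes
#' the likelihood under the detailed-balance constraint by the standard
#' self-consistent fixed-point iteration on the symmetric pair-count
#' variables, `x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)`.
#' Convergence is declared when the maximal relative change of the
#' stationary distribution drops below `tol`; non-convergence within
#' `max_iter` sweeps is an error reporting the residual.
#'
#' @param C transition count matrix (see [count_transitions()]).
#' @param tol convergence tolerance on the stationary distribution
#'   (default 1e-10).
#' @param max_iter maximal number of fixed-point sweeps (default 1e6).
#' @param dt_frame physical time per trajectory frame (default 1; any unit).
#' @param lag lag in frames (default: the `lag` attribute of `C`).
#' @return object of class `msm_model`: `T` (row-stochastic), `pi`,
#'   `eigenvalues` (real, descending), `right_ev`, `left_ev`, `lag`,
#'   `dt_frame`, `active_set` (original state indices), `counts`.
#' @export
estimate_reversible <- function(C, tol = 1e-10, max_iter = 1e6,
                                dt_frame = 1, lag = attr(C, "lag")) {
  if (is.null(lag)) lag <- 1
  active <- largest_connected_set(C)
  Ca <- unclass(as.matrix(C))[active, active, drop = FALSE]
  n <- nrow(Ca)
  ci <- rowSums(Ca)
  if (any(ci == 0)) stop("state with no outgoing counts inside active set")
  Csym <- Ca + t(Ca)
  X <- Csym / sum(Ca)               # initial symmetric pair weights
  xi <- rowSums(X)
  if (n == 1L) {
    T <- matrix(1, 1, 1); pi_st <- 1
  } else {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      denom <- outer(ci / xi, ci / xi, "+")
      X <- Csym / denom
      X[Csym == 0] <- 0
      xi_new <- rowSums(X)
      xi_new <- xi_new  # normalization-free; pi computed below
      delta <- max(abs(xi_new / sum(xi_new) - xi / sum(xi)) /
                     pmax(xi_new / sum(xi_new), 1e-300))
      xi <- xi_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("reversible MLE did not converge: residual %.3g after %d sweeps",
                   delta, as.integer(max_iter)))
    T <- X / xi
    pi_st <- xi / sum(xi)
  }
  T <- T / rowSums(T)               # clean rounding
  eg <- msm_spectrum(T, pi_st)
  structure(list(T = T, pi = pi_st, eigenvalues = eg$values,
                 right_ev = eg$right, left_ev = eg$left,
                 lag = lag, dt_frame = dt_frame, active_set = active,
                 counts = Ca),
            class = "msm_model")
}

# Spectral decomposition of a reversible T via the symmetrized matrix
# S = P^{1/2} T P^{-1/2}: real eigenvalues (descending), pi-orthonormal
# right eigenvectors (first column constant 1) and left = pi * right.
msm_spectrum <- function(T, pi_st) {
  s <- sqrt(pi_st)
  S <- T * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  right <- eg$vectors / s
  sgn <- sign(right[1, 1]); if (sgn == 0) sgn <- 1
  right[, 1] <- abs(right[, 1])     # convention: first eigenvector positive
  left <- eg$vectors * s
  left[, 1] <- left[, 1] * sgn
  list(values = eg$values, right = right, left = left)
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("Reversible MSM: %d microstates, lag %d frames (%g time units)\n",
              length(x$pi), x$lag, x$lag * x$dt_frame))
  k <- min(4, length(x$eigenvalues))
  cat("  leading eigenvalues:", paste(signif(x$eigenvalues[1:k], 4),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Physical lag time of a model
#' @param model an `msm_model`.
#' @export
lag_time <- function(model) model$lag * model$dt_frame

#' Implied timescales across lag times
#'
#' For each lag, estimates a reversible MSM and reports
#' `t_i(tau) = -tau / ln(lambda_i(tau))` in physical units.  Eigenvalues
#' `<= 0` or `>= 1` give `NA` timescales (flagged, not fatal).
#'
#' @param dtrajs discretized trajectories (list of integer vectors).
#' @param lags increasing vector of lags in frames.
#' @param n_timescales how many timescales to report (default 3).
#' @param dt_frame physical time per frame.
#' @return data frame with columns `lag`, `ts2`, `ts3`, ...; class
#'   `implied_timescales`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3, dt_frame = 1) {
  rows <- lapply(lags, function(lg) {
    C <- count_transitions(dtrajs, lg)
    m <- estimate_reversible(C, dt_frame = dt_frame, lag = lg)
    lam <- m$eigenvalues[seq(2, length.out = n_timescales)]
    ts <- safe_timescale(lam, lg * dt_frame)
    c(lag = lg * dt_frame, stats::setNames(ts, paste0("ts", 1 + seq_along(ts))))
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("implied_timescales", "data.frame")
  out
}

#' PCCA++ metastable lumping
#'
#' Soft memberships of microstates to `n_meta` metastable states from the
#' dominant pi-orthonormal right eigenvectors (inner-simplex vertex
#' construction: the most extreme microstates in eigenvector space become
#' the vertices, memberships are the barycentric coordinates, clipped to
#' `[0, 1]` and row-normalized).  For `n_meta = 2` this reduces to a
#' monotone linear transform of the second right eigenvector.
#'
#' @param model an `msm_model` (reversible, connected).
#' @param n_meta number of metastable states (default 2); must not exceed
#'   the number of dominant eigenvalues with a positive spectral gap.
#' @return object of class `pcca_result`: `membership` (n_micro x n_meta,
#'   rows sum to 1), `assignment` (crisp argmax), `coarse_pi` (sums to 1),
#'   `n_meta`.
#' @export
pcca_plus <- function(model, n_meta = 2) {
  stopifnot(inherits(model, "msm_model"))
  lam <- model$eigenvalues
  n <- length(lam)
  if (n_meta < 2) stop("n_meta must be >= 2")
  if (n_meta > n) stop("n_meta exceeds the number of microstates")
  if (n_meta < n && !(lam[n_meta] > lam[n_meta + 1] + 1e-12))
    stop(sprintf("no spectral gap after eigenvalue %d (lambda_%d = %.6f, lambda_%d = %.6f)",
                 n_meta, n_meta, lam[n_meta], n_meta + 1, lam[n_meta + 1]))
  Psi <- model$right_ev[, seq_len(n_meta), drop = FALSE]
  Psi[, 1] <- 1
  chi <- inner_simplex_memberships(Psi)
  chi <- pmin(pmax(chi, 0), 1)
  chi <- chi / rowSums(chi)
  coarse <- as.numeric(crossprod(chi, model$pi))
  structure(list(membership = chi,
                 assignment = max.col(chi, ties.method = "first"),
                 coarse_pi = coarse / sum(coarse), n_meta = n_meta),
            class = "pcca_result")
}

# Vertex search in eigenvector space (Deuflhard-Weber inner simplex):
# pick the row farthest from the origin, then iteratively the row farthest
# from the affine span of the chosen vertices; memberships are the
# barycentric coordinates wrt the vertex simplex.
inner_simplex_memberships <- function(Psi) {
  n <- nrow(Psi); m <- ncol(Psi)
  idx <- integer(m)
  idx[1] <- which.max(rowSums(Psi^2))
  d <- sweep(Psi, 2, Psi[idx[1], ])
  if (m > 1) {
    for (j in 2:m) {
      norms <- rowSums(d^2)
      idx[j] <- which.max(norms)
      v <- d[idx[j], ] / sqrt(norms[idx[j]])
      d <- d - (d %*% v) %*% t(v)
    }
  }
  A <- solve(Psi[idx, , drop = FALSE])
  Psi %*% A
}

#' @export
print.pcca_result <- function(x, ...) {
  cat(sprintf("PCCA++ lumping into %d metastable states\n", x$n_meta))
  cat("  coarse stationary probabilities:",
      paste(signif(x$coarse_pi, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mean first passage time between microstate sets
#'
#' Solves the linear system `m_i = tau + sum_j T_ij m_j` with `m = 0` on the
#' target set and reports the stationary-weighted average of `m` over the
#' source set (pi restricted to the source and renormalized), converted to
#' physical time via the model's lag and frame time.
#'
#' @param model an `msm_model`.
#' @param source,target disjoint, non-empty microstate index sets (1-based,
#'   within the active-set-sized transition matrix).
#' @return mean first passage time in physical units.
#' @export
mfpt <- function(model, source, target) {
  n <- length(model$pi)
  source <- as.integer(source); target <- as.integer(target)
  if (length(source) == 0 || length(target) == 0)
    stop("source and target must be non-empty")
  if (any(c(source, target) < 1) || any(c(source, target) > n))
    stop("state index outside the active set")
  if (length(intersect(source, target)) > 0)
    stop("source and target sets must be disjoint")
  tau <- lag_time(model)
  C <- setdiff(seq_len(n), target)
  A <- diag(length(C)) - model$T[C, C, drop = FALSE]
  m <- numeric(n)
  sol <- tryCatch(solve(A, rep(tau, length(C))),
                  error = function(e) stop("mfpt system is singular: target unreachable from some states"))
  m[C] <- sol
  w <- model$pi[source] / sum(model$pi[source])
  sum(w * m[source])
}

#' Mean first passage times between metastable states
#'
#' @param model an `msm_model`.
#' @param pcca a `pcca_result` for the model.
#' @return named numeric vector of mfpts between all ordered pairs of
#'   metastable states, names `"<from>_to_<to>"` using crisp assignments.
#' @export
mfpt_coarse <- function(model, pcca) {
  sets <- split(seq_along(pcca$assignment), pcca$assignment)
  ids <- names(sets)
  out <- c()
  for (a in ids) for (b in ids) if (a != b)
    out[paste0(a, "_to_", b)] <- mfpt(model, sets[[a]], sets[[b]])
  out
}

#' Chapman-Kolmogorov test on the metastable partition
#'
#' Compares the set-persistence probabilities predicted by the model at lag
#' `tau` propagated to `k * tau` (`w_A' T^k 1_A`, `w_A` the stationary
#' distribution restricted to set A) against the same quantity from models
#' re-estimated at lag `k * tau`, with trajectory-bootstrap error bars on the
#' re-estimates.  `K` is truncated with a warning when the data cannot
#' support the longest lag.
#'
#' @param model an `msm_model` estimated at lag `tau` from `dtrajs`.
#' @param dtrajs the discretized trajectories.
#' @param pcca a `pcca_result` defining the sets.
#' @param K maximal multiple of the lag (default 5).
#' @param n_boot bootstrap resamples for error bars (default 20).
#' @param seed seed for the bootstrap.
#' @return data frame with columns `set`, `k`, `predicted`, `estimated`,
#'   `est_sd`; class `ck_test`.
#' @export
ck_test <- function(model, dtrajs, pcca, K = 5, n_boot = 20, seed = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  max_len <- max(vapply(dtrajs, length, 1L))
  K_ok <- max(1L, min(K, (max_len - 1L) %/% model$lag))
  if (K_ok < K)
    warning(sprintf("insufficient data beyond k = %d; truncating K", K_ok))
  sets <- split(seq_along(pcca$assignment), pcca$assignment)
  persistence <- function(T_mat, pi_st, set) {
    w <- pi_st[set] / sum(pi_st[set])
    sum(w * rowSums(T_mat[set, set, drop = FALSE]))
  }
  persistence_k <- function(T_mat, pi_st, set, k) {
    Tk <- matpow(T_mat, k)
    w <- pi_st[set] / sum(pi_st[set])
    sum(w * rowSums(Tk[set, set, drop = FALSE]))
  }
  est_at <- function(dt_list, k) {
    C <- count_transitions(dt_list, model$lag * k,
                           n_states = max(model$active_set))
    Ck <- C[model$active_set, model$active_set, drop = FALSE]
    attr(Ck, "lag") <- model$lag * k
    m <- estimate_reversible(Ck, dt_frame = model$dt_frame)
    # map sets into the re-estimated model's active set
    map <- match(seq_along(model$active_set), m$active_set)
    vapply(sets, function(s) {
      s2 <- stats::na.omit(map[s])
      if (length(s2) == 0) return(NA_real_)
      persistence(m$T, m$pi, s2)
    }, 1)
  }
  rows <- list()
  boot_idx <- withr::with_seed(seed,
    replicate(n_boot, sample(length(dtrajs), replace = TRUE),
              simplify = FALSE))
  for (k in seq_len(K_ok)) {
    pred <- vapply(sets, function(s) persistence_k(model$T, model$pi, s, k), 1)
    est <- est_at(dtrajs, k)
    boots <- vapply(boot_idx, function(bi)
      tryCatch(est_at(dtrajs[bi], k), error = function(e)
        rep(NA_real_, length(sets))), numeric(length(sets)))
    boots <- matrix(boots, nrow = length(sets))
    sds <- apply(boots, 1, stats::sd, na.rm = TRUE)
    rows[[k]] <- data.frame(set = names(sets), k = k, predicted = pred,
                            estimated = est, est_sd = sds,
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ck_test", "data.frame")
  out
}

matpow <- function(M, k) {
  out <- diag(nrow(M))
  P <- M
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  out
}

#' Trajectory-bootstrap uncertainty of coarse populations and mfpts
#'
#' Resamples whole trajectories with replacement, re-runs count -> trim ->
#' reversible MLE -> PCCA++ -> coarse probabilities and metastable mfpts per
#' resample, and reports 2.5/97.5 percentile intervals.  Metastable state
#' identity across resamples is aligned by maximal microstate overlap with
#' the full-data crisp assignment.  Resamples losing connectivity (or the
#' spectral gap) are skipped and counted; more than 50% skips is an error.
#'
#' @param dtrajs list of discretized trajectories (>= 2).
#' @param lag lag in frames.
#' @param n_meta number of metastable states (default 2).
#' @param n_resamples number of bootstrap resamples (default 100).
#' @param seed integer seed (deterministic output).
#' @param dt_frame physical time per frame.
#' @return object of class `uncertainty_ensemble`: `coarse_pi` and `mfpt`
#'   (matrices, one row per successful resample), `intervals`, `point`
#'   (full-data estimates), `n_skipped`.
#' @export
bootstrap_ensemble <- function(dtrajs, lag, n_meta = 2, n_resamples = 100,
                               seed = 1, dt_frame = 1) {
  if (!is.list(dtrajs) || length(dtrajs) < 2)
    stop("need at least 2 trajectories to bootstrap")
  n_states <- max(vapply(dtrajs, max, 1L))
  fit_once <- function(dt_list) {
    C <- count_transitions(dt_list, lag, n_states = n_states)
    m <- estimate_reversible(C, dt_frame = dt_frame, lag = lag)
    p <- pcca_plus(m, n_meta)
    list(model = m, pcca = p)
  }
  full <- fit_once(dtrajs)
  ref_assign <- rep(NA_integer_, n_states)
  ref_assign[full$model$active_set] <- full$pcca$assignment

  one <- function(dt_list) {
    f <- fit_once(dt_list)
    # align metastable labels with the full-data assignment
    assign_here <- rep(NA_integer_, n_states)
    assign_here[f$model$active_set] <- f$pcca$assignment
    tab <- table(factor(assign_here, levels = seq_len(n_meta)),
                 factor(ref_assign, levels = seq_len(n_meta)))
    perm <- greedy_label_match(tab)
    coarse <- f$pcca$coarse_pi[order(perm)]
    sets <- split(seq_along(f$pcca$assignment), f$pcca$assignment)
    mf <- matrix(NA_real_, n_meta, n_meta)
    for (a in seq_len(n_meta)) for (b in seq_len(n_meta)) if (a != b)
      mf[perm[a], perm[b]] <- mfpt(f$model, sets[[as.character(a)]],
                                   sets[[as.character(b)]])
    list(coarse = coarse, mfpt = mf)
  }

  res_pi <- matrix(NA_real_, n_resamples, n_meta)
  mf_names <- outer(seq_len(n_meta), seq_len(n_meta),
                    function(a, b) paste0(a, "_to_", b))
  offdiag <- which(row(mf_names) != col(mf_names))
  res_mf <- matrix(NA_real_, n_resamples, length(offdiag))
  colnames(res_mf) <- mf_names[offdiag]
  skipped <- 0
  draws <- withr::with_seed(seed,
    replicate(n_resamples, sample(length(dtrajs), replace = TRUE),
              simplify = FALSE))
  for (r in seq_len(n_resamples)) {
    got <- tryCatch(one(dtrajs[draws[[r]]]), error = function(e) NULL)
    if (is.null(got)) { skipped <- skipped + 1; next }
    res_pi[r, ] <- got$coarse
    res_mf[r, ] <- got$mfpt[offdiag]
  }
  if (skipped > n_resamples / 2)
    stop(sprintf("%d of %d bootstrap resamples lost connectivity", skipped,
                 n_resamples))
  ok <- !is.na(res_pi[, 1])
  qfun <- function(M) apply(M, 2, stats::quantile, c(0.025, 0.975),
                            na.rm = TRUE, names = FALSE)
  point_mf <- mfpt_coarse(full$model, full$pcca)
  structure(list(coarse_pi = res_pi[ok, , drop = FALSE],
                 mfpt = res_mf[ok, , drop = FALSE],
                 intervals = list(coarse_pi = qfun(res_pi[ok, , drop = FALSE]),
                                  mfpt = qfun(res_mf[ok, , drop = FALSE])),
                 point = list(coarse_pi = full$pcca$coarse_pi,
                              mfpt = point_mf),
                 model = full$model, pcca = full$pcca,
                 n_skipped = skipped, seed = seed),
            class = "uncertainty_ensemble")
}

# Greedy assignment of resample labels to reference labels by overlap.
greedy_label_match <- function(tab) {
  m <- nrow(tab)
  perm <- integer(m)
  tab <- as.matrix(tab)
  for (step in seq_len(m)) {
    pos <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    perm[pos[1]] <- pos[2]
    tab[pos[1], ] <- -1
    tab[, pos[2]] <- -1
  }
  perm
}

#' @export
print.uncertainty_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d resamples kept, %d skipped\n",
              nrow(x$coarse_pi), x$n_skipped))
  ci <- x$intervals$coarse_pi
  for (j in seq_along(x$point$coarse_pi))
    cat(sprintf("  state %d: pi = %.3f [%.3f, %.3f]\n", j,
                x$point$coarse_pi[j], ci[1, j], ci[2, j]))
  invisible(x)
}
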