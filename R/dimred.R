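#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around the covariance eigendecomposition (via
#' [stats::prcomp()]) returning the mean, eigenvalues (variances, descending)
#' and orthonormal eigenvectors.  Constant data yields all-zero eigenvalues.
#'
#' @param X numeric matrix (>= 2 rows).
#' @return object of class `pca_model` with fields `mean`, `eigenvalues`,
#'   `eigenvectors`, `explained` (fractions; sum 1 unless all eigenvalues
#'   are 0).
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean = pc$center, eigenvalues = ev,
                 eigenvectors = pc$rotation,
                 explained = if (sum(ev) > 0) ev / sum(ev) else ev),
            class = "pca_model")
}

#' Time-lagged independent component analysis
#'
#' Reversible (symmetrized) TICA: solves the generalized eigenproblem
#' `C(tau) v = lambda C(0) v` where both covariances are estimated from the
#' pooled lagged pairs of all trajectories (pairs never cross trajectory
#' boundaries) and symmetrized by averaging forward and time-reversed pairs,
#' which guarantees real eigenvalues with `|lambda| <= 1`.  `C(0)` is
#' regularized by `regularization * mean(diag(C0))` on the diagonal so that
#' near-constant columns (e.g. a binary Na+ indicator) cannot blow up the
#' whitening.
#'
#' @param trajectories a feature matrix or list of feature matrices (one per
#'   trajectory; equal column sets).
#' @param lag lag time in frames (>= 1).  Trajectories not longer than the
#'   lag are excluded with a warning; if all are excluded, an error.
#' @param n_components number of components retained for projection
#'   (default 4).
#' @param regularization diagonal shrinkage strength (default 1e-6).
#' @return object of class `tica_model` with fields `lag`, `mean`, `C0`,
#'   `Ctau`, `eigenvalues` (descending), `eigenvectors` (columns, full set),
#'   `n_components`, `regularization`, `timescales`.
#' @export
fit_tica <- function(trajectories, lag, n_components = 4,
                     regularization = 1e-6) {
  if (is.matrix(trajectories) || is.data.frame(trajectories))
    trajectories <- list(as.matrix(trajectories))
  stopifnot(lag >= 1, n_components >= 1)
  lens <- vapply(trajectories, nrow, 1L)
  ok <- lens > lag
  if (!any(ok)) stop("all trajectories are shorter than the lag")
  if (!all(ok)) {
    warning(sprintf("%d trajectory(ies) shorter than lag %d excluded",
                    sum(!ok), lag))
    trajectories <- trajectories[ok]
  }
  d <- ncol(trajectories[[1]])
  s <- numeric(d); S00 <- matrix(0, d, d); S0t <- matrix(0, d, d); N <- 0
  for (X in trajectories) {
    X <- as.matrix(X)
    n <- nrow(X)
    X0 <- X[1:(n - lag), , drop = FALSE]
    Xt <- X[(1 + lag):n, , drop = FALSE]
    s <- s + colSums(X0) + colSums(Xt)
    S00 <- S00 + crossprod(X0) + crossprod(Xt)
    S0t <- S0t + crossprod(X0, Xt) + crossprod(Xt, X0)
    N <- N + (n - lag)
  }
  mu <- s / (2 * N)
  C0 <- S00 / (2 * N) - tcrossprod(mu)
  Ct <- S0t / (2 * N) - tcrossprod(mu)
  C0 <- (C0 + t(C0)) / 2
  Ct <- (Ct + t(Ct)) / 2
  C0r <- C0 + diag(regularization * mean(diag(C0)), d)
  U <- chol(C0r)
  Li <- backsolve(U, diag(d))          # C0r^{-1/2} (right factor inverse)
  A <- t(Li) %*% Ct %*% Li
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  V <- Li %*% eg$vectors               # generalized eigenvectors
  lam <- eg$values
  if (n_components > d) stop("n_components exceeds feature dimension")
  structure(list(lag = lag, mean = mu, C0 = C0, Ctau = Ct,
                 eigenvalues = lam, eigenvectors = V,
                 n_components = n_components,
                 regularization = regularization,
                 timescales = safe_timescale(lam, lag)),
            class = "tica_model")
}

# -tau / ln(lambda) where defined (0 < lambda < 1), NA otherwise
safe_timescale <- function(lam, tau) {
  out <- rep(NA_real_, length(lam))
  ok <- is.finite(lam) & lam > 0 & lam < 1
  out[ok] <- -tau / log(lam[ok])
  out
}

#' Project data onto a fitted PCA or TICA model
#'
#' Centers `X` with the training mean and multiplies by the retained
#' eigenvectors; columns are named `PC1...` / `TIC1...`.
#'
#' @param model a `pca_model` or `tica_model`.
#' @param X matrix with the training column count.
#' @param n_components components to keep (defaults: all for PCA, the
#'   model's `n_components` for TICA); must be >= 1.
#' @return projected matrix.
#' @export
project <- function(model, X, n_components = NULL) UseMethod("project")

#' @export
project.pca_model <- function(model, X, n_components = NULL) {
  if (is.null(n_components)) n_components <- ncol(model$eigenvectors)
  project_impl(model$mean, model$eigenvectors, X, n_components, "PC")
}

#' @export
project.tica_model <- function(model, X, n_components = NULL) {
  if (is.null(n_components)) n_components <- model$n_components
  project_impl(model$mean, model$eigenvectors, X, n_components, "TIC")
}

project_impl <- function(mu, V, X, k, prefix) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(mu))
  X <- as.matrix(X)
  if (ncol(X) != length(mu))
    stop(sprintf("X has %d columns; model expects %d", ncol(X), length(mu)))
  if (k < 1) stop("need at least one retained component")
  if (k > ncol(V)) stop("n_components exceeds available components")
  Y <- sweep(X, 2, mu) %*% V[, seq_len(k), drop = FALSE]
  colnames(Y) <- paste0(prefix, seq_len(k))
  Y
}

#' Serialize a PCA/TICA model to JSON
#'
#' @param model a `pca_model` or `tica_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- lapply(unclass(model), function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x)) else x)
  obj$class <- class(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
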