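#' k-means microstate discretization (k-means++ / Lloyd)
#'
#' k-means++ initialization followed by Lloyd iterations until the maximal
#' center shift falls below `tol` or `max_iter` is reached.  Deterministic
#' given `seed`.  An iteration that empties a cluster re-seeds that center
#' from the point farthest from its current center.  The within-cluster sum
#' of squares (inertia) is asserted to be non-increasing across iterations.
#'
#' @param X numeric matrix (n x d) of reduced coordinates.
#' @param k number of clusters (`1 <= k <= n`).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol Lloyd stopping parameters.
#' @return object of class `kmeans_model`: `centers` (k x d), `seed`,
#'   `inertia`, `iterations`, `labels` (training assignment).
#' @export
kmeans_fit <- function(X, k, seed = 1234, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds the number of points n = %d", k, n))
  if (k < 1) stop("k must be >= 1")
  centers <- withr::with_seed(seed, kmeanspp_init(X, k))
  inertia_prev <- Inf
  it <- 0
  repeat {
    it <- it + 1
    d2 <- dist2_to_centers(X, centers)
    lab <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), lab)])
    if (inertia > inertia_prev + 1e-8 * max(1, inertia_prev))
      stop("internal error: k-means inertia increased")
    new_centers <- centers
    for (j in seq_len(k)) {
      mem <- lab == j
      if (!any(mem)) {  # empty cluster: re-seed from the farthest point
        far <- which.max(d2[cbind(seq_len(n), lab)])
        new_centers[j, ] <- X[far, ]
      } else {
        new_centers[j, ] <- colMeans(X[mem, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    inertia_prev <- inertia
    if (shift < tol || it >= max_iter) break
  }
  d2 <- dist2_to_centers(X, centers)
  lab <- max.col(-d2, ties.method = "first")
  structure(list(centers = centers, seed = seed,
                 inertia = sum(d2[cbind(seq_len(n), lab)]),
                 iterations = it, labels = lab, k = k),
            class = "kmeans_model")
}

# squared Euclidean distances, n x k
dist2_to_centers <- function(X, centers) {
  d2 <- -2 * X %*% t(centers)
  d2 <- sweep(d2, 1, rowSums(X^2), "+")
  d2 <- sweep(d2, 2, rowSums(centers^2), "+")
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Assign frames to the nearest k-means center
#'
#' Euclidean nearest-center assignment; ties broken by the lowest center
#' index.
#'
#' @param model a `kmeans_model`.
#' @param X matrix of reduced coordinates, or a list of such matrices (one
#'   per trajectory).
#' @return integer vector of 1-based microstate labels, or a list of vectors
#'   (the discretized trajectories).
#' @export
assign_clusters <- function(model, X) {
  if (is.list(X) && !is.data.frame(X))
    return(lapply(X, assign_clusters, model = model))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centers))
    stop(sprintf("X has %d columns; centers have %d", ncol(X),
                 ncol(model$centers)))
  max.col(-dist2_to_centers(X, model$centers), ties.method = "first")
}

#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#'
#' UPGMA agglomeration via [stats::hclust()]; the flat partition with
#' `n_clusters` clusters is obtained by cutting after the `(n - k)`-th merge
#' ([stats::cutree()] with `k`).  Per cluster, the representative is the
#' medoid: the member minimizing the mean distance to its co-members.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param n_clusters requested number of flat clusters.
#' @return object of class `linkage_result`: `merge`, `height` (non-
#'   decreasing), `labels` (1-based), `representatives` (medoid index per
#'   cluster), `order_by_size` (cluster ids, descending population).
#' @export
average_linkage <- function(D, n_clusters) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be non-negative with zero diagonal")
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters out of range")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- unname(stats::cutree(hc, k = n_clusters))
  reps <- vapply(seq_len(n_clusters), function(cl) {
    mem <- which(labels == cl)
    if (length(mem) == 1L) return(mem)
    mem[which.min(rowMeans(D[mem, mem, drop = FALSE]))]
  }, 1L)
  sizes <- tabulate(labels, n_clusters)
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 representatives = reps,
                 order_by_size = order(sizes, decreasing = TRUE),
                 sizes = sizes, n_clusters = n_clusters),
            class = "linkage_result")
}

#' Pairwise Kabsch RMSD matrix of ensemble frames
#'
#' @param ensemble a `traj_ensemble`.
#' @param selection atom indices used for both fitting and RMSD.
#' @param fit_selection optional separate fit selection.
#' @param frames frame indices (default all).
#' @return symmetric matrix of RMSD values (Angstrom).
#' @export
pairwise_rmsd <- function(ensemble, selection, fit_selection = selection,
                          frames = seq_len(n_frames(ensemble))) {
  nf <- length(frames)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    fi <- ensemble$coords[, , frames[i], drop = TRUE]
    for (j in (i + 1):nf) {
      fj <- ensemble$coords[, , frames[j], drop = TRUE]
      D[i, j] <- D[j, i] <- kabsch_rmsd(fi, fj, fit_selection, selection)$rmsd
    }
  }
  D
}

#' Representative (medoid) frames per structural cluster
#'
#' For each cluster label, the frame minimizing the mean Kabsch RMSD to its
#' co-members; clusters are reported in descending population order (the
#' paper-style "most populated clusters first" convention).
#'
#' @param ensemble a `traj_ensemble`.
#' @param labels integer cluster label per frame (all frames covered).
#' @param selection atom indices for the RMSD (fit and measurement).
#' @return data frame with one row per cluster, ordered by descending size:
#'   `cluster`, `size`, `medoid_frame`.
#' @export
select_medoids <- function(ensemble, labels, selection) {
  if (length(labels) != n_frames(ensemble))
    stop("labels must cover every frame")
  cl_ids <- sort(unique(labels))
  if (length(cl_ids) == 0) stop("empty label set")
  rows <- lapply(cl_ids, function(cl) {
    mem <- which(labels == cl)
    med <- if (length(mem) == 1L) mem else {
      D <- pairwise_rmsd(ensemble, selection, frames = mem)
      mem[which.min(rowMeans(D))]
    }
    data.frame(cluster = cl, size = length(mem), medoid_frame = med)
  })
  out <- do.call(rbind, rows)
  out[order(out$size, decreasing = TRUE), , drop = FALSE]
}
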