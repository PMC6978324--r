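# Shared fixtures: built in code at test time, kept small.

# default study-condition potential
default_spec <- function() potential_spec()

# a fast-mixing symmetric double well for short sampling tests
quick_spec <- function() {
  potential_spec(well_depths = c(E = 2, Estar = 2), barrier_height = 1,
                 sodium_coupling = 1)
}

# random reversible transition matrix from a random symmetric weight matrix
random_reversible_T <- function(n, seed) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * n, 0.05, 1), n, n)
    X <- X + t(X)
    list(T = X / rowSums(X), pi = rowSums(X) / sum(X))
  })
}

# msm_model wrapper around a known reversible T (bypasses counting)
model_from_T <- function(T, pi_st = NULL, lag = 1, dt_frame = 1) {
  if (is.null(pi_st)) {
    e <- eigen(t(T))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    pi_st <- v / sum(v)
  }
  C <- diag(pi_st) %*% T * 1e6  # symmetric for reversible T
  attr(C, "lag") <- lag
  estimate_reversible(C, dt_frame = dt_frame, lag = lag)
}

# metastable 4-state chain: two 2-state blocks with weak coupling
metastable_T4 <- function(eps = 0.01) {
  T <- matrix(c(0.88, 0.10, eps, eps,
                0.10, 0.88, eps, eps,
                eps, eps, 0.90, 0.08,
                eps, eps, 0.08, 0.90), 4, 4, byrow = TRUE)
  T / rowSums(T)
}

# tiny labelled ensemble for feature tests: coordinates set directly
make_toy_ensemble <- function(coords_list, sodium = TRUE, dt_ps = 10,
                              condition = "without_Na") {
  top <- toy_protease_topology(sodium = sodium)
  co <- array(NA_real_, c(nrow(top), 3, length(coords_list)))
  for (i in seq_along(coords_list)) co[, , i] <- coords_list[[i]]
  trajectory_ensemble(top, co, dt_ps = dt_ps, condition = condition)
}

# one embedded frame at a given latent point
embed_point <- function(z, sodium_state = 0, spec = default_spec()) {
  lt <- msmshift:::latent_trajectory(matrix(z, 1, 2), dt = 1e-3, seed = 1,
                                     sodium_state = sodium_state)
  embed_latent_to_structures(lt)
}

# standard error of a time-average from batch means (accounts for
# autocorrelation); x a numeric vector, n_blocks batches
batch_se <- function(x, n_blocks = 20) {
  n <- length(x)
  block <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * block + 1):(b * block)]), 1)
  stats::sd(means) / sqrt(n_blocks)
}
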