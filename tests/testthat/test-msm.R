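test_that("transition counting matches enumeration and the sliding-window total", {
  C <- count_transitions(c(1L, 2L), lag = 1)
  expect_equal(unclass(C)[1:2, 1:2], matrix(c(0L, 0L, 1L, 0L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(C, "total"), 1L)

  set.seed(8)
  d <- sample.int(5, 1000, replace = TRUE)
  C3 <- count_transitions(d, lag = 3)
  brute <- matrix(0L, 5, 5)
  for (t in 1:(1000 - 3)) brute[d[t], d[t + 3]] <- brute[d[t], d[t + 3]] + 1L
  expect_equal(unclass(C3), brute, ignore_attr = TRUE)

  two <- list(sample.int(3, 100, replace = TRUE),
              sample.int(3, 100, replace = TRUE))
  expect_equal(attr(count_transitions(two, lag = 10), "total"), 180L)
  expect_error(count_transitions(list(1:3), lag = 5), "shorter than the lag")
})

test_that("largest strongly connected set matches a reachability oracle", {
  Cfull <- matrix(1L, 3, 3)
  expect_equal(largest_connected_set(Cfull), 1:3)

  blocks <- matrix(0L, 6, 6)
  blocks[1:4, 1:4] <- 1L
  blocks[5:6, 5:6] <- 1L
  expect_equal(largest_connected_set(blocks), 1:4)

  # random sparse graphs vs a matrix-power reachability oracle
  scc_oracle <- function(C) {
    A <- (C > 0) | diag(nrow(C)) > 0
    R <- A
    for (k in seq_len(nrow(C))) R <- (R %*% A + R) > 0  # transitive closure
    mutual <- R & t(R)
    comp <- apply(mutual, 1, function(r) paste(which(r), collapse = ","))
    sizes <- table(comp)
    members <- which(comp == names(sizes)[which.max(sizes)])
    sort(members)
  }
  set.seed(19)
  for (r in 1:5) {
    C <- matrix(rbinom(900, 1, 0.06), 30, 30)
    expect_equal(largest_connected_set(C), scc_oracle(C))
  }
})

test_that("reversible MLE reproduces closed forms, an optimizer oracle and sampled chains", {
  # symmetric counts: T is the row-normalized count matrix
  Cs <- matrix(c(10, 3, 0, 3, 8, 2, 0, 2, 6), 3, 3, byrow = TRUE)
  m <- estimate_reversible(Cs)
  expect_equal(m$T, Cs / rowSums(Cs), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$pi, rowSums(Cs) / sum(Cs), tolerance = 1e-9)

  # asymmetric 3-state counts vs direct likelihood maximization over the
  # symmetric pair-weight parameterization (independent optimizer oracle)
  Ca <- matrix(c(50, 12, 3, 7, 40, 9, 5, 14, 60), 3, 3, byrow = TRUE)
  ml <- estimate_reversible(Ca)
  nll <- function(theta) {
    X <- matrix(0, 3, 3)
    X[upper.tri(X, diag = TRUE)] <- exp(theta)
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    T <- X / rowSums(X)
    -sum(Ca * log(T))
  }
  opt <- optim(rep(0, 6), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  Xo <- matrix(0, 3, 3)
  Xo[upper.tri(Xo, diag = TRUE)] <- exp(opt$par)
  Xo[lower.tri(Xo)] <- t(Xo)[lower.tri(Xo)]
  To <- Xo / rowSums(Xo)
  expect_equal(ml$T, To, tolerance = 1e-6, ignore_attr = TRUE)

  # parameter recovery from a sampled chain within 3 binomial SE per entry
  truth <- metastable_T4(0.02)
  d <- sample_markov_chain(truth, 1e5, seed = 23)
  mr <- estimate_reversible(count_transitions(d, 1))
  n_i <- tabulate(d[-length(d)], 4)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt(truth[i, j] * (1 - truth[i, j]) / n_i[i])
    expect_lt(abs(mr$T[i, j] - truth[i, j]), 3 * se + 1e-3)
  }

  # model invariants: stochasticity, stationarity, detailed balance
  expect_lt(max(abs(rowSums(mr$T) - 1)), 1e-10)
  expect_lt(max(abs(mr$pi %*% mr$T - mr$pi)), 1e-8)
  expect_lt(max(abs(mr$pi * mr$T - t(mr$pi * mr$T))), 1e-8)
})

test_that("detailed balance holds across random count matrices", {
  set.seed(66)
  for (r in 1:20) {
    n <- sample(3:6, 1)
    C <- matrix(rpois(n * n, 4) + 1L, n, n)  # strictly positive: connected
    m <- estimate_reversible(C)
    expect_lt(max(abs(m$pi * m$T - t(m$pi * m$T))), 1e-8)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
    expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  }
})

test_that("implied timescales match spectral ground truth and flag undefined values", {
  # 2-state chain with lambda_2 = e^{-1}: t2 = 1 lag unit
  lam <- exp(-1)
  T2 <- matrix(c((1 + lam) / 2, (1 - lam) / 2,
                 (1 - lam) / 2, (1 + lam) / 2), 2, 2, byrow = TRUE)
  m <- model_from_T(T2)
  expect_equal(-1 / log(m$eigenvalues[2]), 1, tolerance = 1e-8)

  # flat ITS curve across lags for Markovian data
  truth <- metastable_T4(0.015)
  ds <- lapply(1:4, function(s) sample_markov_chain(truth, 5e4, seed = s))
  its <- implied_timescales(ds, lags = c(1, 2, 5, 10), n_timescales = 1)
  t2_true <- -1 / log(sort(eigen(truth)$values, decreasing = TRUE)[2])
  expect_true(all(abs(its$ts2 - t2_true) / t2_true < 0.2))

  # period-2 deterministic data: lambda_2 = -1, timescale undefined (NA)
  alt <- rep(c(1L, 2L), 50)
  its_alt <- implied_timescales(list(alt), lags = 1, n_timescales = 1)
  expect_true(is.na(its_alt$ts2))
})

test_that("PCCA++ lumps metastable blocks and keeps memberships normalized", {
  # near-crisp two-block chain: memberships ~ {0,1}, coarse pi ~ block sums
  T_eps <- function(eps) {
    T <- matrix(c(0.7, 0.3 - eps, eps / 2, eps / 2,
                  0.2, 0.8 - eps, eps / 2, eps / 2,
                  eps / 2, eps / 2, 0.6, 0.4 - eps,
                  eps / 2, eps / 2, 0.5, 0.5 - eps), 4, 4, byrow = TRUE)
    T / rowSums(T)
  }
  m_tiny <- model_from_T(T_eps(1e-10))
  p_tiny <- pcca_plus(m_tiny, 2)
  expect_lt(max(pmin(p_tiny$membership, 1 - p_tiny$membership)), 1e-6)
  block_pi <- c(sum(m_tiny$pi[1:2]), sum(m_tiny$pi[3:4]))
  got <- sort(p_tiny$coarse_pi)
  expect_equal(got, sort(block_pi), tolerance = 1e-8)

  # epsilon-coupled blocks: coarse pi within 1e-2 of the block sums
  m_eps <- model_from_T(T_eps(1e-3))
  p_eps <- pcca_plus(m_eps, 2)
  expect_equal(sort(p_eps$coarse_pi),
               sort(c(sum(m_eps$pi[1:2]), sum(m_eps$pi[3:4]))),
               tolerance = 1e-2)

  # membership rows sum to 1 for random reversible models
  for (r in 1:20) {
    rt <- random_reversible_T(5, seed = 200 + r)
    mp <- pcca_plus(model_from_T(rt$T, rt$pi), 2)
    expect_equal(unname(rowSums(mp$membership)), rep(1, 5), tolerance = 1e-8)
    expect_true(all(mp$membership >= -1e-12 & mp$membership <= 1 + 1e-12))
    expect_equal(sum(mp$coarse_pi), 1, tolerance = 1e-12)
  }

  # degenerate spectrum (no positive gap after lambda_2) is refused
  expect_error(pcca_plus(model_from_T(matrix(1 / 3, 3, 3)), 2), "gap")
})

test_that("mean first passage times solve the linear system and match Monte Carlo", {
  # symmetric 2-state coin chain: mfpt = 1/p = 2 lag units
  T_coin <- matrix(0.5, 2, 2)
  m_coin <- model_from_T(T_coin, c(0.5, 0.5))
  expect_equal(mfpt(m_coin, 1, 2), 2)

  # absorbing one-step case: m = tau
  T_abs <- matrix(c(0, 1, 0.5, 0.5), 2, 2, byrow = TRUE)
  m_abs <- model_from_T(T_abs)
  expect_equal(mfpt(m_abs, 1, 2), 1)

  # 4-state chain vs direct first-passage sampling (Monte Carlo oracle)
  truth <- metastable_T4(0.05)
  mt <- model_from_T(truth)
  m_pred <- mfpt(mt, 1, 4)
  cum <- t(apply(truth, 1, cumsum))
  sample_fp <- function(n_rep, seed) {
    withr::with_seed(seed, vapply(seq_len(n_rep), function(r) {
      s <- 1L; steps <- 0L
      repeat {
        s <- findInterval(runif(1), cum[s, ]) + 1L
        steps <- steps + 1L
        if (s == 4L) return(steps)
      }
    }, 1L))
  }
  fp <- sample_fp(4000, seed = 77)
  se <- sd(fp) / sqrt(length(fp))
  expect_lt(abs(mean(fp) - m_pred), 3 * se)

  # pi-ratio identity on strictly two-state models
  for (r in 1:5) {
    ab <- withr::with_seed(300 + r, runif(2, 0.05, 0.6))
    T2 <- matrix(c(1 - ab[1], ab[1], ab[2], 1 - ab[2]), 2, 2, byrow = TRUE)
    m2 <- model_from_T(T2)
    expect_equal(mfpt(m2, 1, 2) / mfpt(m2, 2, 1), m2$pi[1] / m2$pi[2],
                 tolerance = 1e-10)
  }

  expect_error(mfpt(m_coin, 1, 1), "disjoint")
  expect_error(mfpt(m_coin, integer(0), 1), "non-empty")
})

test_that("Chapman-Kolmogorov test validates Markovian data and flags hidden states", {
  truth <- metastable_T4(0.02)
  ds <- lapply(1:6, function(s) sample_markov_chain(truth, 3e4, seed = 10 + s))
  m <- estimate_reversible(count_transitions(ds, 1))
  p <- pcca_plus(m, 2)
  ck <- ck_test(m, ds, p, K = 5, n_boot = 10, seed = 2)

  # k = 1: predicted and re-estimated coincide by construction
  k1 <- ck[ck$k == 1, ]
  expect_lt(max(abs(k1$predicted - k1$estimated)), 1e-12)
  # Markovian data: agreement within 3 bootstrap SE everywhere
  expect_true(all(abs(ck$predicted - ck$estimated) <=
                    3 * pmax(ck$est_sd, 1e-4)))

  # planted violation: observe a 3-state chain through a 2-state lens
  T3 <- matrix(c(0.98, 0.02, 0.0,
                 0.05, 0.90, 0.05,
                 0.0, 0.02, 0.98), 3, 3, byrow = TRUE)
  lump <- c(1L, 2L, 2L)  # hidden third state folded into observed state 2
  ds3 <- lapply(1:6, function(s) lump[sample_markov_chain(T3, 3e4, seed = 40 + s)])
  m3 <- estimate_reversible(count_transitions(ds3, 1))
  p3 <- pcca_plus(m3, 2)
  ck3 <- ck_test(m3, ds3, p3, K = 5, n_boot = 10, seed = 3)
  worst <- max(abs(ck3$predicted - ck3$estimated) / pmax(ck3$est_sd, 1e-6))
  expect_gt(worst, 3)
})

test_that("trajectory bootstrap quantifies uncertainty with calibrated coverage", {
  truth <- metastable_T4(0.02)
  # identical trajectories: zero-width intervals
  d0 <- sample_markov_chain(truth, 5e3, seed = 1)
  same <- list(d0, d0, d0)
  b0 <- bootstrap_ensemble(same, lag = 1, n_resamples = 10, seed = 4)
  expect_equal(b0$intervals$coarse_pi[1, ], b0$intervals$coarse_pi[2, ],
               tolerance = 1e-12)

  # single resample: degenerate interval at that estimate
  ds <- lapply(1:4, function(s) sample_markov_chain(truth, 5e3, seed = s))
  b1 <- bootstrap_ensemble(ds, lag = 1, n_resamples = 1, seed = 5)
  expect_equal(nrow(b1$coarse_pi), 1)
  expect_equal(b1$intervals$coarse_pi[1, ], b1$intervals$coarse_pi[2, ],
               tolerance = 1e-12)

  # coverage experiment: nominal 95% intervals cover the true coarse pi
  # in at least 90 of 100 repetitions; the trajectory bootstrap needs enough
  # independent units to be calibrated, so each repetition resamples 16
  # trajectories
  ev <- eigen(t(truth)); v <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  pi_true <- v / sum(v)
  block_true <- c(sum(pi_true[1:2]), sum(pi_true[3:4]))
  cover <- 0
  for (rep_i in 1:100) {
    dd <- lapply(1:16, function(s)
      sample_markov_chain(truth, 1000, seed = 1000 * rep_i + s))
    bb <- tryCatch(
      bootstrap_ensemble(dd, lag = 1, n_resamples = 100, seed = rep_i),
      error = function(e) NULL)
    if (is.null(bb)) next
    ci <- bb$intervals$coarse_pi
    lo <- sort(ci[1, ]); hi <- sort(ci[2, ])
    tg <- sort(block_true)
    if (all(tg >= lo - 1e-12 & tg <= hi + 1e-12)) cover <- cover + 1
  }
  expect_gte(cover, 90)

  # intervals bracket the point estimate
  b <- bootstrap_ensemble(ds, lag = 1, n_resamples = 50, seed = 6)
  ci <- b$intervals$coarse_pi
  pt <- sort(b$point$coarse_pi)
  expect_true(all(sort(ci[1, ]) <= pt + 0.05 & sort(ci[2, ]) >= pt - 0.05))
})
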