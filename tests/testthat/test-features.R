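test_that("multi-model PDB writing and reading preserve coordinates and insertion codes", {
  spec <- default_spec()
  lt <- simulate_overdamped(spec, 1, n_steps = 9, seed = 4)
  ens <- embed_latent_to_structures(lt)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure_ensemble(ens, tf)
  back <- read_structure_ensemble(tf, dt_ps = ens$dt_ps,
                                  condition = ens$condition)
  expect_equal(n_frames(back), 10)
  expect_lt(max(abs(back$coords - ens$coords)), 1e-3)  # PDB precision
  expect_true("221a" %in% msmshift:::resid_string(back$topology))

  # single-model file -> one frame
  one <- embed_point(c(0, 0))
  tf1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_ensemble(one, tf1)
  expect_equal(n_frames(read_structure_ensemble(tf1)), 1)

  # requesting a residue the file lacks names it
  no221a <- toy_protease_topology()
  no221a <- no221a[!(no221a$resno == 221 & no221a$insert == "a"), ]
  class(no221a) <- class(toy_protease_topology())
  ens2 <- trajectory_ensemble(no221a, array(rnorm(nrow(no221a) * 3),
                                            c(nrow(no221a), 3, 1)))
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_ensemble(ens2, tf2)
  expect_error(read_structure_ensemble(tf2, required_residues = "221a"),
               "221a")
})

test_that("frames TSV plus topology PDB round-trips an ensemble", {
  ens <- embed_latent_to_structures(
    simulate_overdamped(default_spec(), 0, n_steps = 4, seed = 8))
  top_pdb <- withr::local_tempfile(fileext = ".pdb")
  frames <- withr::local_tempfile(fileext = ".tsv")
  write_structure_ensemble(ens, top_pdb)
  write_frames_tsv(ens, frames)
  back <- read_structure_ensemble(frames, format = "tsv",
                                  topology_path = top_pdb)
  expect_equal(back$coords, ens$coords, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("kabsch rmsd is zero under rigid motion and matches a quaternion-grid oracle", {
  set.seed(21)
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_rmsd(A, A, 1:5)$rmsd, 0, tolerance = 1e-12)

  th <- 0.5 * pi
  R90 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% R90 + matrix(c(3, -1, 2), 5, 3, byrow = TRUE)
  f <- kabsch_rmsd(B, A, 1:5)
  expect_lt(f$rmsd, 1e-10)
  expect_equal(det(f$rotation), 1, tolerance = 1e-10)

  # brute-force oracle: minimize rmsd over rotations parameterized by
  # quaternions, coarse grid + local refinement, independent of the SVD path
  mob <- matrix(rnorm(15), 5, 3)
  refc <- matrix(rnorm(15), 5, 3)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  }
  Ac <- sweep(mob, 2, colMeans(mob)); Bc <- sweep(refc, 2, colMeans(refc))
  obj <- function(q) sqrt(mean(rowSums((Ac %*% t(quat_rot(q)) - Bc)^2)))
  grid <- as.matrix(expand.grid(w = c(-1, -0.3, 0.3, 1), x = c(-1, -0.3, 0.3, 1),
                                y = c(-1, -0.3, 0.3, 1), z = c(-1, -0.3, 0.3, 1)))
  vals <- apply(grid, 1, obj)
  best <- optim(grid[which.min(vals), ], obj,
                control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(kabsch_rmsd(mob, refc, 1:5)$rmsd, best$value, tolerance = 1e-6)

  # symmetry when fit and rmsd selections coincide
  expect_equal(kabsch_rmsd(mob, refc, 1:5)$rmsd,
               kabsch_rmsd(refc, mob, 1:5)$rmsd, tolerance = 1e-9)

  expect_error(kabsch_rmsd(mob, refc[1:4, ], 1:5), "differ in size")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))  # collinear points
  expect_error(kabsch_superpose(coll, coll + 1), "degenerate")
})

test_that("dihedral angles follow the IUPAC convention and an independent oracle", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)
  set.seed(33)
  for (i in 1:10) {
    q <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(q))),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(dihedral_angle(p1, p1, p3, c(1, 1, 0)), "degenerate")
})

test_that("activation features match constructed geometry and are rigid-motion invariant", {
  top <- toy_protease_topology(sodium = FALSE)
  base <- embed_point(c(0.4, -0.3))$coords[, , 1]
  ens <- make_toy_ensemble(list(base))
  F <- compute_activation_features(ens)
  # hand-computed COM distance for the 3-atom W215 group
  w_idx <- atom_select(ens$topology, "215")
  triad_idx <- vapply(c("57", "102", "195"),
                      function(r) atom_select(ens$topology, r, "CA")[1], 1L)
  wct_hand <- sqrt(sum((colMeans(base[w_idx, ]) -
                          colMeans(base[triad_idx, ]))^2))
  expect_equal(unname(F[1, "WCT"]), wct_hand, tolerance = 1e-10)

  # constructed frame with the W215 COM exactly 5 Angstrom from the triad COM
  tcen <- colMeans(base[triad_idx, ])
  shift <- base
  w_com <- colMeans(base[w_idx, ])
  dirv <- c(0, 1, 0)
  shift[w_idx, ] <- sweep(base[w_idx, ], 2, w_com) +
    matrix(tcen + 5 * dirv, length(w_idx), 3, byrow = TRUE)
  F5 <- compute_activation_features(make_toy_ensemble(list(shift)))
  expect_equal(unname(F5[1, "WCT"]), 5, tolerance = 1e-10)

  # rigid motion leaves all four features unchanged
  th <- 0.77
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- base %*% R + matrix(c(11, -4, 6), nrow(base), 3, byrow = TRUE)
  Fm <- compute_activation_features(make_toy_ensemble(list(moved)))
  expect_equal(unname(Fm[1, ]), unname(F[1, ]), tolerance = 1e-9)

  # missing anchor atoms are reported by residue
  noW <- top[top$resno != 215, ]
  class(noW) <- class(top)
  ensW <- trajectory_ensemble(noW, array(0, c(nrow(noW), 3, 1)))
  expect_error(compute_activation_features(ensW), "215")
})

test_that("sodium indicator is a strict conjunction of the two anchor distances", {
  top <- toy_protease_topology()
  base <- embed_point(c(0, 0), sodium_state = 0)$coords[, , 1]
  o1 <- atom_select(top, "221a", "O")[1]
  o2 <- atom_select(top, "224", "O")[1]
  na_i <- which(top$element == "Na")
  place_na <- function(d1, d2) {
    # anchors are 5 apart on the y axis; solve for a point at (d1, d2)
    a <- base[o1, ]; b <- base[o2, ]
    u <- (b - a) / 5
    x <- (d1^2 - d2^2 + 25) / 10        # distance along the axis
    h2 <- d1^2 - x^2
    stopifnot(h2 >= 0)
    perp <- c(0, 0, 1)
    fr <- base
    fr[na_i, ] <- a + x * u + sqrt(h2) * perp
    fr
  }
  ens <- make_toy_ensemble(list(place_na(3.7, 3.7), place_na(3.0, 3.9),
                                place_na(3.8, 3.8), place_na(5.0, 5.0)))
  expect_equal(na_bound_indicator(ens), c(1L, 0L, 1L, 0L), ignore_attr = TRUE)
  # no sodium particle at all: all zeros, no error
  ens0 <- embed_point(c(0, 0))
  ens0$topology <- ens0$topology[ens0$topology$element != "Na", ]
  ens0$coords <- ens0$coords[seq_len(nrow(ens0$topology)), , , drop = FALSE]
  expect_equal(na_bound_indicator(ens0), 0L, ignore_attr = TRUE)
})

test_that("residue COM features use geometric centers and respect alignment", {
  ens <- embed_latent_to_structures(
    simulate_overdamped(default_spec(), 0, n_steps = 3, seed = 12))
  X <- residue_com_features(ens, align = FALSE)
  # single-atom residues: COM equals the atom position (G216 CA)
  g216 <- atom_select(ens$topology, "216", "CA")[1]
  expect_equal(unname(X[2, c("216_x", "216_y", "216_z")]),
               unname(ens$coords[g216, , 2]), tolerance = 1e-12)
  # duplicated frame gives identical rows
  co <- ens$coords[, , c(1, 1), drop = FALSE]
  ens2 <- trajectory_ensemble(ens$topology, co, dt_ps = 1)
  X2 <- residue_com_features(ens2, align = TRUE)
  expect_equal(X2[1, ], X2[2, ], tolerance = 1e-10)
  # unweighted vs mass-weighted conventions differ for mixed-element residues
  Xw <- residue_com_features(ens, align = FALSE, weighted = TRUE)
  r221 <- c("221_x", "221_y", "221_z")  # N/C/O mixture
  expect_false(isTRUE(all.equal(X[, r221], Xw[, r221], tolerance = 1e-8)))
  # unweighted matches a by-hand geometric mean of the residue's atoms
  idx221 <- atom_select(ens$topology, "221")
  expect_equal(unname(X[1, r221]), unname(colMeans(ens$coords[idx221, , 1])),
               tolerance = 1e-12)
  attr_com <- attr(X, "com")
  expect_identical(attr_com, "unweighted")
})

test_that("psi dihedrals are extracted for residues with a complete quartet", {
  ens <- embed_latent_to_structures(
    simulate_overdamped(default_spec(), 0, n_steps = 5, seed = 3))
  psi <- psi_dihedrals(ens)
  expect_true("psi_221" %in% colnames(psi))
  expect_equal(nrow(psi), 6)
  # cross-check one residue against the direct dihedral call
  top <- ens$topology
  q <- c(atom_select(top, "221", "N")[1], atom_select(top, "221", "CA")[1],
         atom_select(top, "221", "C")[1], atom_select(top, "221a", "N")[1])
  direct <- dihedral_angle(ens$coords[q[1], , 1], ens$coords[q[2], , 1],
                           ens$coords[q[3], , 1], ens$coords[q[4], , 1])
  expect_equal(unname(psi[1, "psi_221"]), direct, tolerance = 1e-10)
})
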