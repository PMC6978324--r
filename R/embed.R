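#' Embed a latent double-well trajectory into toy 3D structures
#'
#' Deterministic smooth map from the 2D latent space onto coordinates of the
#' labelled toy topology, constructed so that the geometric activation
#' descriptors read back the latent state:
#'
#' * the first latent coordinate `z1` monotonically controls the D221 phi
#'   torsion, `PhiD = 115 * tanh(z1)` degrees, positive in the E well
#'   (`z1 = +1`) and negative in the E* well, and also modulates RCT;
#' * the second latent coordinate `z2` controls WCT (`10 + z2` Angstrom) and
#'   GG (`7 + 0.8 * z2` Angstrom);
#' * with `sodium_state = 1` the Na+ particle sits midway between the
#'   backbone oxygens of R221a and K224 (2.5 Angstrom from each, inside the
#'   3.8 Angstrom coordination cutoff); with `sodium_state = 0` it is parked
#'   80 Angstrom away.
#'
#' At the default E well center (1, 0) the embedded reference values are
#' therefore WCT = 10, GG = 7, RCT = 12 - 1.5 tanh(1) ~ 10.86 and
#' PhiD = +87.6 degrees.
#'
#' @param latent a `latent_trajectory`.
#' @param template a labelled topology (default [toy_protease_topology()]);
#'   a missing required atom raises an error naming it.
#' @return a `traj_ensemble` with one frame per latent frame; `dt_ps` is the
#'   latent `dt` (reduced time units stored as the frame spacing).
#' @export
embed_latent_to_structures <- function(latent,
                                       template = toy_protease_topology()) {
  stopifnot(inherits(latent, "latent_trajectory"))
  top <- template
  need <- list(
    c("57", "CA"), c("102", "CA"), c("195", "CA"),
    c("193", "CA"), c("216", "CA"),
    c("215", NA),                       # any W215 heavy atoms
    c("220", "C"), c("221", "N"), c("221", "CA"), c("221", "C"),
    c("221a", "CZ"), c("221a", "O"), c("224", "O"))
  idx <- lapply(need, function(nd) {
    elety <- if (is.na(nd[2])) NULL else nd[2]
    atom_select(top, nd[1], elety)
  })
  names(idx) <- vapply(need, function(nd)
    paste0(nd[1], "_", ifelse(is.na(nd[2]), "heavy", nd[2])), "")
  na_idx <- which(top$element == "Na")

  z <- latent$positions
  nf <- nrow(z)
  phi <- 115 * tanh(z[, 1])          # degrees, monotone in z1
  wct <- 10 + z[, 2]
  gg <- 7 + 0.8 * z[, 2]
  rct <- 12 - 1.5 * tanh(z[, 1])

  # fixed scaffold
  triad <- rbind(`57` = c(20, 0, 0), `102` = c(22.4, 1.2, 0),
                 `195` = c(21.0, -1.8, 1.2))
  tcen <- colMeans(triad)
  u_w <- c(0, 1, 0)                  # W215 COM direction from triad center
  u_r <- c(0, 0, 1)                  # R221a CZ direction from triad center
  w_off <- rbind(c(1.2, 0, 0.6), c(-1.2, 0.8, -0.3), c(0, -0.8, -0.3))
  g193 <- c(5, 10, 0); u_g <- c(1, 0, 0)
  q0 <- c(40, 0, 0)                  # phi quartet anchor
  p_c220 <- q0 + c(-1.2, 0.9, 0)
  p_n221 <- q0
  p_ca221 <- q0 + c(1.45, 0, 0)
  o_r221a <- c(50, 0, 0)             # Na+ anchor oxygens, 5 A apart
  o_k224 <- c(50, 5, 0)
  na_on <- (o_r221a + o_k224) / 2
  na_off <- c(80, 80, 80)
  r221a_bb <- rbind(N = q0 + c(3.2, 0.5, 0.5), CA = q0 + c(4.4, 1.1, 0.7),
                    C = q0 + c(5.7, 0.4, 1.0))

  coords <- array(NA_real_, c(nrow(top), 3, nf))
  set_atom <- function(i, mat) coords[i, , ] <<- t(mat)  # mat: nf x 3
  rep_row <- function(v) matrix(v, nf, 3, byrow = TRUE)

  set_atom(idx[["57_CA"]], rep_row(triad[1, ]))
  set_atom(idx[["102_CA"]], rep_row(triad[2, ]))
  set_atom(idx[["195_CA"]], rep_row(triad[3, ]))
  # W215 heavy group: COM at tcen + wct * u_w, rigid internal offsets
  w_idx <- idx[["215_heavy"]]
  n_w <- length(w_idx)
  com_w <- rep_row(tcen) + outer(wct, u_w)
  offs <- w_off[seq_len(min(n_w, 3)), , drop = FALSE]
  if (n_w > 3) offs <- rbind(offs, matrix(0, n_w - 3, 3))
  offs <- sweep(offs, 2, colMeans(offs))  # zero-mean so COM is exact
  for (a in seq_len(n_w))
    set_atom(w_idx[a], com_w + rep_row(offs[a, ]))
  set_atom(idx[["193_CA"]], rep_row(g193))
  set_atom(idx[["216_CA"]], rep_row(g193) + outer(gg, u_g))
  set_atom(idx[["221a_CZ"]], rep_row(tcen) + outer(rct, u_r))
  set_atom(idx[["220_C"]], rep_row(p_c220))
  set_atom(idx[["221_N"]], rep_row(p_n221))
  set_atom(idx[["221_CA"]], rep_row(p_ca221))
  c221 <- t(vapply(seq_len(nf), function(i)
    place_dihedral_atom(p_c220, p_n221, p_ca221, phi[i]), numeric(3)))
  set_atom(idx[["221_C"]], c221)
  o221 <- atom_select(top, "221", "O", required = FALSE)
  if (length(o221) > 0) set_atom(o221, c221 + rep_row(c(0.4, 1.1, 0.3)))
  set_atom(idx[["221a_O"]], rep_row(o_r221a))
  set_atom(idx[["224_O"]], rep_row(o_k224))
  for (nm in c("N", "CA", "C")) {
    ii <- atom_select(top, "221a", nm, required = FALSE)
    if (length(ii) > 0) set_atom(ii, rep_row(r221a_bb[nm, ]))
  }
  if (length(na_idx) > 0)
    set_atom(na_idx, rep_row(if (latent$sodium_state == 1) na_on else na_off))

  if (any(is.na(coords)))
    stop("internal error: embedding left atoms unplaced")
  trajectory_ensemble(top, coords, dt_ps = latent$dt,
                      condition = if (latent$sodium_state == 1) "with_Na"
                                  else "without_Na",
                      source = sprintf("embedded latent seed %d", latent$seed))
}
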