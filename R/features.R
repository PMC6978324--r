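#' Activation-state descriptors of a protease ensemble
#'
#' Computes, per frame, the four geometric descriptors that separate the
#' active (E) and inactive (E*) conformations of a chymotrypsin-family
#' protease:
#'
#' * `WCT` -- distance between the center of mass of the W215 heavy atoms and
#'   the center of the catalytic-triad C-alpha atoms (Angstrom);
#' * `RCT` -- distance between the guanidinium C (CZ) of R221a and the triad
#'   C-alpha center (Angstrom);
#' * `GG`  -- distance between the C-alpha atoms of G193 and G216, the
#'   S1-pocket occlusion coordinate (Angstrom);
#' * `PhiD` -- the phi backbone dihedral of D221 (degrees), the slow torsion
#'   of the Na+ binding loop.
#'
#' Centers of mass are unweighted (geometric) centers of the heavy atoms;
#' this convention is recorded in the `units`/`com` attributes and a
#' mass-weighted mode can be selected via `weighted`.
#'
#' @param ensemble a `traj_ensemble`.
#' @param triad residue ids of the catalytic triad (default H57, D102, S195).
#' @param weighted use mass-weighted centers instead of geometric centers.
#' @return numeric matrix (frames x 4) with columns `WCT`, `RCT`, `GG`,
#'   `PhiD`; attributes `units` and `com`.
#' @export
compute_activation_features <- function(ensemble,
                                        triad = c("57", "102", "195"),
                                        weighted = FALSE) {
  top <- ensemble$topology
  triad_idx <- vapply(triad, function(r) atom_select(top, r, "CA")[1], 1L)
  w_idx <- atom_select(top, "215")
  cz_idx <- atom_select(top, "221a", "CZ")[1]
  g193 <- atom_select(top, "193", "CA")[1]
  g216 <- atom_select(top, "216", "CA")[1]
  phi_idx <- phi_quartet(top, "221")

  co <- ensemble$coords
  com <- function(idx) group_com(co, idx, top, weighted)  # 3 x nf
  tcen <- com(triad_idx)
  dist3 <- function(a, b) sqrt(colSums((a - b)^2))
  wct <- dist3(com(w_idx), tcen)
  rct <- dist3(com(cz_idx), tcen)
  gg <- dist3(com(g193), com(g216))
  phid <- dihedral_angle(t(co[phi_idx[1], , ]), t(co[phi_idx[2], , ]),
                         t(co[phi_idx[3], , ]), t(co[phi_idx[4], , ]))
  out <- cbind(WCT = wct, RCT = rct, GG = gg, PhiD = phid)
  attr(out, "units") <- c(WCT = "A", RCT = "A", GG = "A", PhiD = "deg")
  attr(out, "com") <- if (weighted) "mass-weighted" else "unweighted"
  out
}

# phi backbone quartet of a residue: C of the preceding residue in topology
# order, then N, CA, C of the residue itself.
phi_quartet <- function(top, resid) {
  res <- topology_residues(top)
  key <- paste0(res$resno, res$insert)
  pos <- match(resid, key)
  if (is.na(pos)) stop(sprintf("residue %s not found in topology", resid))
  if (pos == 1L) stop(sprintf("residue %s has no preceding residue for phi",
                              resid))
  prev <- key[pos - 1L]
  c(atom_select(top, prev, "C")[1],
    atom_select(top, resid, "N")[1],
    atom_select(top, resid, "CA")[1],
    atom_select(top, resid, "C")[1])
}

# psi backbone quartet: N, CA, C of the residue, N of the following residue.
psi_quartet <- function(top, resid) {
  res <- topology_residues(top)
  key <- paste0(res$resno, res$insert)
  pos <- match(resid, key)
  if (is.na(pos)) stop(sprintf("residue %s not found in topology", resid))
  if (pos == nrow(res)) return(NULL)
  nxt <- key[pos + 1L]
  nn <- atom_select(top, nxt, "N", required = FALSE)
  if (length(nn) == 0) return(NULL)
  c(atom_select(top, resid, "N")[1],
    atom_select(top, resid, "CA")[1],
    atom_select(top, resid, "C")[1], nn[1])
}

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 Na = 22.99, P = 30.974)

# center of an atom group over all frames; returns 3 x n_frames
group_com <- function(coords, idx, top, weighted = FALSE) {
  sub <- coords[idx, , , drop = FALSE]
  if (weighted) {
    m <- ATOMIC_MASS[top$element[idx]]
    if (any(is.na(m))) m[is.na(m)] <- 12
    apply(sub, c(2, 3), stats::weighted.mean, w = m)
  } else {
    apply(sub, c(2, 3), mean)
  }
}

#' Binary Na+ coordination indicator
#'
#' 1 for a frame iff at least one Na+ particle is simultaneously within
#' `cutoff` of the backbone oxygen of R221a **and** of the backbone oxygen of
#' K224; systems without Na+ particles give all zeros.
#'
#' @param ensemble a `traj_ensemble`.
#' @param cutoff coordination cutoff in Angstrom (default 3.8).
#' @return integer vector (frames) in `{0, 1}`, attribute `units = "binary"`.
#' @export
na_bound_indicator <- function(ensemble, cutoff = 3.8) {
  top <- ensemble$topology
  na_idx <- which(top$element == "Na")
  nf <- n_frames(ensemble)
  if (length(na_idx) == 0) {
    out <- integer(nf)
  } else {
    o1 <- ensemble$coords[atom_select(top, "221a", "O")[1], , , drop = TRUE]
    o2 <- ensemble$coords[atom_select(top, "224", "O")[1], , , drop = TRUE]
    if (nf == 1L) { o1 <- matrix(o1, 3, 1); o2 <- matrix(o2, 3, 1) }
    bound <- rep(FALSE, nf)
    for (ia in na_idx) {
      na <- ensemble$coords[ia, , , drop = TRUE]
      if (nf == 1L) na <- matrix(na, 3, 1)
      d1 <- sqrt(colSums((na - o1)^2))
      d2 <- sqrt(colSums((na - o2)^2))
      bound <- bound | (d1 <= cutoff & d2 <= cutoff)
    }
    out <- as.integer(bound)
  }
  attr(out, "units") <- "binary"
  out
}

#' Residue-wise center-of-mass features of the Na+ binding loop
#'
#' Per-residue unweighted heavy-atom centers of mass after global C-alpha
#' superposition of every frame onto a reference frame -- raw Cartesian
#' centers would be dominated by rigid-body motion.  Columns are
#' `<resid>_x/_y/_z` per residue, 3 columns per residue.
#'
#' @param ensemble a `traj_ensemble`.
#' @param residues character vector of residue ids; default: every residue of
#'   the topology with number in 213..229 (the Na+ binding loop), insertion
#'   codes included, in topology order.
#' @param align superpose frames on C-alpha atoms first (default `TRUE`).
#' @param reference_frame frame used as alignment reference.
#' @param weighted mass-weighted centers instead of geometric.
#' @return numeric matrix (frames x 3 * n_residues).
#' @export
residue_com_features <- function(ensemble, residues = NULL, align = TRUE,
                                 reference_frame = 1, weighted = FALSE) {
  top <- ensemble$topology
  if (is.null(residues)) {
    res <- topology_residues(top)
    keep <- res$resno >= 213 & res$resno <= 229
    residues <- paste0(res$resno[keep], res$insert[keep])
    if (length(residues) == 0) stop("no residues in the 213..229 loop range")
  }
  idx_list <- lapply(residues, function(r) atom_select(top, r))
  co <- ensemble$coords
  nf <- n_frames(ensemble)
  if (align) {
    ca_idx <- which(top$elety == "CA" & top$element == "C")
    if (length(ca_idx) < 3) stop("need >= 3 C-alpha atoms for superposition")
    ref <- co[ca_idx, , reference_frame, drop = TRUE]
    co_aligned <- co
    for (i in seq_len(nf)) {
      fit <- kabsch_superpose(co[ca_idx, , i, drop = TRUE], ref)
      co_aligned[, , i] <- sweep(co[, , i, drop = TRUE] %*% fit$rotation, 2,
                                 fit$translation, "+")
    }
    co <- co_aligned
  }
  cols <- lapply(seq_along(residues), function(k)
    t(group_com(co, idx_list[[k]], top, weighted)))
  out <- do.call(cbind, cols)
  colnames(out) <- paste0(rep(residues, each = 3), "_", c("x", "y", "z"))
  attr(out, "units") <- "A"
  attr(out, "com") <- if (weighted) "mass-weighted" else "unweighted"
  attr(out, "aligned") <- align
  out
}

#' Backbone psi dihedrals per residue
#'
#' @param ensemble a `traj_ensemble`.
#' @param residues residue ids; default: every residue for which the psi
#'   quartet (N, CA, C and the next residue's N) is resolvable.
#' @return matrix (frames x residues) of psi angles in degrees, columns
#'   `psi_<resid>`.
#' @export
psi_dihedrals <- function(ensemble, residues = NULL) {
  top <- ensemble$topology
  if (is.null(residues)) {
    res <- topology_residues(top)
    residues <- paste0(res$resno, res$insert)
  }
  quads <- lapply(residues, function(r) {
    q <- tryCatch(psi_quartet(top, r), error = function(e) NULL)
    q
  })
  ok <- !vapply(quads, is.null, TRUE)
  if (!any(ok)) stop("no residue with a resolvable psi quartet")
  residues <- residues[ok]; quads <- quads[ok]
  co <- ensemble$coords
  out <- vapply(quads, function(q)
    dihedral_angle(t(co[q[1], , , drop = TRUE]), t(co[q[2], , , drop = TRUE]),
                   t(co[q[3], , , drop = TRUE]), t(co[q[4], , , drop = TRUE])),
    numeric(n_frames(ensemble)))
  out <- matrix(out, nrow = n_frames(ensemble))
  colnames(out) <- paste0("psi_", residues)
  attr(out, "units") <- "deg"
  out
}

#' Write a feature matrix as TSV with a JSON metadata sidecar
#'
#' @param X feature matrix with named columns.
#' @param path output TSV path; units and conventions go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(X, path) {
  utils::write.table(data.frame(frame = seq_len(nrow(X)), X,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(columns = colnames(X),
                            units = attr(X, "units"),
                            com = attr(X, "com")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
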