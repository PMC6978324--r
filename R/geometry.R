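#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` by singular value
#' decomposition, with the usual reflection correction so the returned
#' rotation is proper (determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (same n, n >= 3).
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` superposes onto `reference`, and
#'   `rmsd` of the fit atoms after superposition.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference selections differ in size")
  if (nrow(mobile) < 3) stop("need at least 3 atoms for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1))
    stop("degenerate (collinear) fit selection")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # so that t(R) maps A -> B
  R <- t(R)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

#' Kabsch-aligned RMSD with separate fit and measurement selections
#'
#' Superposes `mobile` onto `reference` using the `fit_selection` atoms (e.g.
#' C-alpha), then measures the RMSD over `rmsd_selection` (e.g. all heavy
#' atoms) -- the alignment convention of targeted-MD restraints.
#'
#' @param mobile,reference full-frame n x 3 coordinate matrices.
#' @param fit_selection,rmsd_selection integer atom indices into the frames;
#'   `rmsd_selection` defaults to the fit selection.
#' @return list with `rotation`, `translation` and `rmsd` (Angstrom).
#' @export
kabsch_rmsd <- function(mobile, reference, fit_selection,
                        rmsd_selection = fit_selection) {
  if (length(fit_selection) == 0 || length(rmsd_selection) == 0)
    stop("selections must be non-empty")
  n_min <- min(nrow(mobile), nrow(reference))
  if (max(fit_selection, rmsd_selection) > n_min)
    stop("selection out of bounds: mobile and reference frames differ in size")
  fit <- kabsch_superpose(mobile[fit_selection, , drop = FALSE],
                          reference[fit_selection, , drop = FALSE])
  moved <- sweep(mobile[rmsd_selection, , drop = FALSE] %*% fit$rotation, 2,
                 fit$translation, "+")
  delta <- moved - reference[rmsd_selection, , drop = FALSE]
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = sqrt(mean(rowSums(delta^2))))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention (clockwise positive when viewed from p2 towards
#' p3); range (-180, 180] degrees.  Planar trans is 180 degrees, planar cis
#' is 0.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, or n x 3 matrices for vectorized
#'   evaluation over n quadruples.
#' @return dihedral angle(s) in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as3 <- function(p) if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
  p1 <- as3(p1); p2 <- as3(p2); p3 <- as3(p3); p4 <- as3(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  nrm <- function(a) sqrt(rowSums(a^2))
  if (any(nrm(b1) < 1e-12) || any(nrm(b2) < 1e-12) || any(nrm(b3) < 1e-12))
    stop("degenerate dihedral: consecutive points coincide")
  if (any(nrm(n1) < 1e-12) || any(nrm(n2) < 1e-12))
    stop("degenerate dihedral: three consecutive points are collinear")
  m <- cross(n1, b2 / nrm(b2))
  ang <- -atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  if (nrow(p1) == 1L) ang[1] else ang
}

# Place the fourth atom of a dihedral quadruple so that the dihedral
# (p1, p2, p3, p4) equals `angle_deg` under the convention above, given
# p1, p2, p3 and bond length / angle parameters.  Used by the embedding.
place_dihedral_atom <- function(p1, p2, p3, angle_deg, bond = 1.5,
                                bond_angle_deg = 111) {
  b2 <- p3 - p2; e_z <- b2 / sqrt(sum(b2^2))
  b1 <- p2 - p1
  # component of -b1 orthogonal to the axis defines the zero of the dihedral
  perp <- -b1 + sum(b1 * e_z) * e_z
  e_x <- perp / sqrt(sum(perp^2))
  e_y <- c(e_z[2] * e_x[3] - e_z[3] * e_x[2],
           e_z[3] * e_x[1] - e_z[1] * e_x[3],
           e_z[1] * e_x[2] - e_z[2] * e_x[1])
  th <- (180 - bond_angle_deg) * pi / 180  # deviation from axis continuation
  phi <- angle_deg * pi / 180
  p3 + bond * (cos(th) * e_z + sin(th) * (cos(phi) * e_x + sin(phi) * e_y))
}
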