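#' Trajectory ensemble container
#'
#' Ordered frames of 3D coordinates over a fixed topology, with per-trajectory
#' metadata: the time between stored frames, the sodium condition and a free
#' source tag.
#'
#' @param topology a topology data frame (see [toy_protease_topology()]).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param dt_ps time between stored frames, picoseconds (> 0).
#' @param condition `"without_Na"` or `"with_Na"`.
#' @param source free-text provenance tag.
#' @return object of class `traj_ensemble`.
#' @export
trajectory_ensemble <- function(topology, coords, dt_ps = 10,
                                condition = c("without_Na", "with_Na"),
                                source = "") {
  condition <- match.arg(condition)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(topology), dt_ps > 0)
  if (any(!is.finite(coords))) stop("coordinates contain non-finite values")
  structure(list(topology = topology, coords = coords, dt_ps = dt_ps,
                 condition = condition, source = source),
            class = "traj_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble a `traj_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d atoms, %d frames, dt %g ps, %s\n",
              nrow(x$topology), n_frames(x), x$dt_ps, x$condition))
  invisible(x)
}

#' Extract one frame as an n x 3 coordinate matrix
#' @param ensemble a `traj_ensemble`.
#' @param i frame index.
#' @export
get_frame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  ensemble$coords[, , i, drop = TRUE]
}

#' Write an ensemble as a multi-model PDB file
#'
#' wwPDB 3.3 ATOM records, one MODEL/ENDMDL block per frame; insertion codes
#' preserved verbatim.
#'
#' @param ensemble a `traj_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_ensemble <- function(ensemble, path) {
  top <- ensemble$topology
  nf <- n_frames(ensemble)
  xyz <- matrix(aperm(ensemble$coords, c(2, 1, 3)), nrow = nf,
                byrow = TRUE)  # frames x (3 * n_atoms), atom-major triples
  bio3d::write.pdb(file = path, xyz = xyz, resno = top$resno,
                   resid = top$resname, elety = top$elety,
                   chain = top$chain, insert = ifelse(top$insert == "", NA,
                                                      top$insert),
                   elesy = top$element)
  invisible(path)
}

#' Read a structure ensemble
#'
#' Supports multi-model PDB (via bio3d) and a plain-text pair of a frames TSV
#' (written by [write_frames_tsv()]) plus a topology PDB.
#'
#' @param path PDB file, or frames TSV when `format = "tsv"`.
#' @param format `"pdb"` or `"tsv"`.
#' @param topology_path topology PDB for `format = "tsv"`.
#' @param dt_ps,condition,source metadata attached to the ensemble.
#' @param required_residues optional character vector of residue ids (e.g.
#'   `"221a"`) that must be present; missing ones raise an error naming them.
#' @return a `traj_ensemble`.
#' @export
read_structure_ensemble <- function(path, format = c("pdb", "tsv"),
                                    topology_path = NULL, dt_ps = 10,
                                    condition = "without_Na", source = path,
                                    required_residues = NULL) {
  format <- match.arg(format)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    top <- data.frame(elety = pdb$atom$elety, resname = pdb$atom$resid,
                      chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                      resno = pdb$atom$resno,
                      insert = ifelse(is.na(pdb$atom$insert), "",
                                      pdb$atom$insert),
                      element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                       substr(pdb$atom$elety, 1, 1),
                                       pdb$atom$elesy),
                      stringsAsFactors = FALSE)
    class(top) <- c("topology", "data.frame")
    nf <- nrow(pdb$xyz)
    coords <- array(aperm(array(t(pdb$xyz), c(3, nrow(top), nf)), c(2, 1, 3)),
                    c(nrow(top), 3, nf))
  } else {
    if (is.null(topology_path))
      stop("format 'tsv' needs a topology_path (topology PDB)")
    ref <- read_structure_ensemble(topology_path, "pdb", dt_ps = dt_ps,
                                   condition = condition, source = source)
    top <- ref$topology
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    mat <- as.matrix(tab[, setdiff(colnames(tab), "frame"), drop = FALSE])
    if (ncol(mat) != 3 * nrow(top))
      stop(sprintf("frames TSV has %d coordinate columns; topology implies %d",
                   ncol(mat), 3 * nrow(top)))
    coords <- array(aperm(array(t(mat), c(3, nrow(top), nrow(mat)), ),
                          c(2, 1, 3)), c(nrow(top), 3, nrow(mat)))
  }
  ens <- trajectory_ensemble(top, coords, dt_ps = dt_ps,
                             condition = condition, source = source)
  if (!is.null(required_residues)) {
    present <- resid_string(top)
    missing <- setdiff(required_residues, present)
    if (length(missing) > 0)
      stop(sprintf("required residue(s) missing from %s: %s", path,
                   paste(missing, collapse = ", ")))
  }
  ens
}

#' Write ensemble frames as TSV
#'
#' One row per frame, columns `frame` then `x/y/z` per atom; a JSON sidecar
#' `<path>.json` records the metadata.
#'
#' @param ensemble a `traj_ensemble`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(ensemble, path) {
  nf <- n_frames(ensemble)
  mat <- matrix(aperm(ensemble$coords, c(2, 1, 3)), nrow = nf, byrow = TRUE)
  lab <- resid_string(ensemble$topology)
  colnames(mat) <- paste0(rep(paste0(lab, "_", ensemble$topology$elety),
                              each = 3), "_", c("x", "y", "z"))
  df <- data.frame(frame = seq_len(nf), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dt_ps = ensemble$dt_ps,
                            condition = ensemble$condition,
                            source = ensemble$source,
                            n_atoms = nrow(ensemble$topology),
                            n_frames = nf),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a latent or discrete trajectory as TSV with a JSON sidecar
#'
#' @param x a `latent_trajectory` or an integer state vector from
#'   [sample_markov_chain()].
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(x, path) {
  if (inherits(x, "latent_trajectory")) {
    df <- data.frame(step = seq_len(nrow(x$positions)) - 1L, x$positions)
    if (!is.null(x$bias_log))
      df <- cbind(df, rbind(x$bias_log, NA))  # bias log has one row per step
    meta <- list(kind = "latent", dt = x$dt, seed = x$seed,
                 sodium_state = x$sodium_state,
                 targeted = !is.null(x$bias_log))
  } else {
    df <- data.frame(step = seq_along(x) - 1L, state = as.integer(x))
    meta <- list(kind = "discrete", lag_unit = attr(x, "lag_unit"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
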