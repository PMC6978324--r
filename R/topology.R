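#' Toy protease topology for the synthetic embedding
#'
#' A minimal labelled topology carrying exactly the atoms the activation-state
#' descriptors need, in chymotrypsin numbering with insertion codes:
#' catalytic-triad C-alpha atoms (H57, D102, S195), G193 and G216 C-alpha
#' (S1-pocket occlusion distance GG), the heavy-atom group of W215 (WCT),
#' the backbone phi quartet of D221 (PhiD; C of the preceding residue A220
#' plus N/CA/C of D221), the guanidinium C and backbone O of R221a (RCT and
#' the Na+ anchor), the backbone O of K224 (second Na+ anchor) and, when
#' `sodium = TRUE`, one Na+ particle.
#'
#' @param sodium include a Na+ particle (default `TRUE`).
#' @return data frame of class `c("topology", "data.frame")` with columns
#'   `elety` (atom name), `resname`, `chain`, `resno`, `insert` (insertion
#'   code, `""` when absent) and `element`.
#' @export
toy_protease_topology <- function(sodium = TRUE) {
  atom <- function(elety, resname, resno, insert = "", element = substr(elety, 1, 1),
                   chain = "A") {
    data.frame(elety = elety, resname = resname, chain = chain,
               resno = as.integer(resno), insert = insert, element = element,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    atom("CA", "HIS", 57, element = "C"),
    atom("CA", "ASP", 102, element = "C"),
    atom("CA", "GLY", 193, element = "C"),
    atom("CA", "SER", 195, element = "C"),
    atom("CG",  "TRP", 215, element = "C"),
    atom("CD2", "TRP", 215, element = "C"),
    atom("CZ2", "TRP", 215, element = "C"),
    atom("CA", "GLY", 216, element = "C"),
    atom("C",  "ALA", 220, element = "C"),
    atom("N",  "ASP", 221, element = "N"),
    atom("CA", "ASP", 221, element = "C"),
    atom("C",  "ASP", 221, element = "C"),
    atom("O",  "ASP", 221, element = "O"),
    atom("N",  "ARG", 221, "a", element = "N"),
    atom("CA", "ARG", 221, "a", element = "C"),
    atom("C",  "ARG", 221, "a", element = "C"),
    atom("O",  "ARG", 221, "a", element = "O"),
    atom("CZ", "ARG", 221, "a", element = "C"),
    atom("O",  "LYS", 224, element = "O")
  )
  if (sodium)
    rows <- rbind(rows, atom("NA", "NA", 900, element = "Na", chain = "I"))
  class(rows) <- c("topology", "data.frame")
  rows
}

# "221a" -> list(resno = 221, insert = "a"); "215" -> insert ""
parse_resid <- function(resid) {
  m <- regmatches(resid, regexec("^([0-9]+)([A-Za-z]?)$", resid))[[1]]
  if (length(m) == 0) stop(sprintf("malformed residue id '%s'", resid))
  list(resno = as.integer(m[2]), insert = m[3])
}

resid_string <- function(top) paste0(top$resno, top$insert)

#' Atom indices by residue id and atom name
#'
#' @param top a topology data frame.
#' @param resid residue id string in chymotrypsin numbering, insertion code
#'   appended (e.g. `"221a"`).
#' @param elety atom name(s), or `NULL` for all atoms of the residue.
#' @param heavy_only drop hydrogens.
#' @param required error (naming residue and atom) when nothing matches.
#' @return integer vector of row indices into `top`.
#' @export
atom_select <- function(top, resid, elety = NULL, heavy_only = TRUE,
                        required = TRUE) {
  r <- parse_resid(resid)
  sel <- top$resno == r$resno & top$insert == r$insert
  if (!is.null(elety)) sel <- sel & top$elety %in% elety
  if (heavy_only) sel <- sel & top$element != "H"
  idx <- which(sel)
  if (required && length(idx) == 0)
    stop(sprintf("residue %s%s not found in topology", resid,
                 if (!is.null(elety)) paste0(" (atom ", paste(elety, collapse = "/"), ")")
                 else ""))
  idx
}

# Unique residues in topology order, as a data frame (resno, insert, resname).
topology_residues <- function(top) {
  key <- paste(top$chain, top$resno, top$insert)
  first <- !duplicated(key)
  data.frame(resno = top$resno[first], insert = top$insert[first],
             resname = top$resname[first], chain = top$chain[first],
             stringsAsFactors = FALSE)
}
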