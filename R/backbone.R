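# Backbone structures: per-residue N, CA, C, O (optionally amide H)
# coordinates in Angstrom for a single conformation of one peptide.

#' Construct a backbone structure
#'
#' A `backbone_structure` holds one conformation of a peptide as per-residue
#' backbone-atom coordinates (N, CA, C, O and optionally the amide H), in
#' Angstrom. Most users will not call this directly but obtain structures
#' from [build_from_dihedrals()], [generate_ensemble()] or
#' [read_multimodel_pdb()].
#'
#' @param sequence a [peptide_sequence()] (or string coercible to one).
#' @param coords numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param atom character vector of atom names ("N", "CA", "C", "O", "H"),
#'   one per row of `coords`.
#' @param resno integer vector of 1-based residue indices, one per row.
#' @param validate check atom completeness and bonded distances.
#' @return An object of class `backbone_structure` with elements `sequence`,
#'   `coords`, `atom`, `resno`.
#' @export
backbone_structure <- function(sequence, coords, atom, resno,
                               validate = TRUE) {
  sequence <- as_peptide_sequence(sequence)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("backbone_structure: coords must be an n x 3 matrix")
  atom <- as.character(atom)
  resno <- as.integer(resno)
  if (nrow(coords) != length(atom) || nrow(coords) != length(resno))
    stop("backbone_structure: coords, atom and resno lengths differ")
  s <- structure(list(sequence = sequence, coords = coords,
                      atom = atom, resno = resno),
                 class = "backbone_structure")
  if (validate) validate_backbone(s)
  s
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %s: %d residues, %d atoms (%s)\n",
              seq_name(x$sequence), length(x$sequence), nrow(x$coords),
              paste(sort(unique(x$atom)), collapse = ",")))
  invisible(x)
}

n_residues <- function(s) length(s$sequence)

# n_res x 3 matrix of coordinates for one named backbone atom;
# rows of missing atoms are NA.
atom_xyz <- function(s, name) {
  n <- n_residues(s)
  out <- matrix(NA_real_, n, 3)
  sel <- s$atom == name
  out[s$resno[sel], ] <- s$coords[sel, , drop = FALSE]
  out
}

has_atom <- function(s, name, resno) {
  any(s$atom == name & s$resno == resno)
}

validate_backbone <- function(s) {
  n <- n_residues(s)
  for (a in c("N", "CA", "C", "O")) {
    cnt <- tabulate(s$resno[s$atom == a], nbins = n)
    if (any(cnt != 1L))
      stop("backbone_structure: residue(s) ",
           paste(which(cnt != 1L), collapse = ","),
           " must carry exactly one ", a, " atom")
  }
  ncnt <- tabulate(s$resno[s$atom == "H"], nbins = n)
  if (any(ncnt > 1L))
    stop("backbone_structure: duplicate amide H atoms")
  N <- atom_xyz(s, "N"); CA <- atom_xyz(s, "CA"); C <- atom_xyz(s, "C")
  d_nca <- sqrt(rowSums((CA - N)^2))
  d_cac <- sqrt(rowSums((C - CA)^2))
  bad <- d_nca < 1 | d_nca > 2 | d_cac < 1 | d_cac > 2
  if (n > 1) {
    d_cn <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    bad[-n] <- bad[-n] | d_cn < 1 | d_cn > 2
  }
  if (any(bad))
    stop("backbone_structure: bonded backbone distances outside [1, 2] A ",
         "at residue(s) ", paste(which(bad), collapse = ","))
  invisible(TRUE)
}

# stack all frames' CA coordinates etc. -- small helpers used across modules
backbone_masses <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999,
                     H = 1.008)

atom_masses <- function(s) unname(backbone_masses[s$atom])
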