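# DSSP-style secondary-structure assignment from backbone hydrogen-bond
# patterns (Kabsch-Sander electrostatic model), plus classification of
# (phi, psi) points into canonical Ramachandran regions.

#' Place amide hydrogens on a backbone
#'
#' Adds the amide H to residues 2..n (except proline, which has no amide
#' hydrogen) using the DSSP convention: H sits 1.0 A from N along the unit
#' vector opposite the previous residue's C -> O direction, i.e. along
#' (C_prev - O_prev). Residues already carrying an H are left untouched, so
#' the operation is idempotent.
#'
#' @param s a [backbone_structure()].
#' @return The structure with amide hydrogens present.
#' @export
place_amide_hydrogens <- function(s) {
  stopifnot(inherits(s, "backbone_structure"))
  n <- n_residues(s)
  C <- atom_xyz(s, "C"); O <- atom_xyz(s, "O"); N <- atom_xyz(s, "N")
  H <- atom_xyz(s, "H")
  add_xyz <- NULL; add_res <- integer(0)
  for (i in 2:n) {
    if (!is.na(H[i, 1])) next          # existing H preserved
    if (s$sequence[i] == "P") next     # proline has no amide H
    if (is.na(O[i - 1, 1]))
      stop("place_amide_hydrogens: missing O on residue ", i - 1)
    h <- N[i, ] + unit(C[i - 1, ] - O[i - 1, ])
    add_xyz <- rbind(add_xyz, h); add_res <- c(add_res, i)
  }
  if (length(add_res)) {
    s$coords <- rbind(s$coords, add_xyz)
    s$atom <- c(s$atom, rep("H", length(add_res)))
    s$resno <- c(s$resno, add_res)
  }
  s
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic hydrogen-bond energy between the amide group (N-H) of a
#' donor residue and the carbonyl group (C=O) of an acceptor residue:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A hydrogen bond is declared when `E < -0.5` kcal/mol. Donor and acceptor
#' roles are not interchangeable. Donor and acceptor must be at least two
#' residues apart in sequence.
#'
#' @param s a [backbone_structure()] carrying amide hydrogens (see
#'   [place_amide_hydrogens()]).
#' @param donor,acceptor 1-based residue indices.
#' @return Energy in kcal/mol.
#' @export
kabsch_sander_energy <- function(s, donor, acceptor) {
  if (abs(donor - acceptor) < 2)
    stop("kabsch_sander_energy: donor and acceptor must be >= 2 residues apart")
  N <- atom_xyz(s, "N"); H <- atom_xyz(s, "H")
  C <- atom_xyz(s, "C"); O <- atom_xyz(s, "O")
  if (is.na(H[donor, 1]))
    stop("kabsch_sander_energy: donor residue lacks an amide H")
  r <- function(a, b) vnorm(a - b)
  r_on <- r(O[acceptor, ], N[donor, ]); r_ch <- r(C[acceptor, ], H[donor, ])
  r_oh <- r(O[acceptor, ], H[donor, ]); r_cn <- r(C[acceptor, ], N[donor, ])
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    stop("kabsch_sander_energy: overlapping atoms (r < 0.5 A)")
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# n x n logical matrix: hbond[i, j] TRUE when N-H of residue i donates to
# C=O of residue j with Kabsch-Sander energy < -0.5 kcal/mol. Vectorized;
# pairs closer than |i - j| < 2 and donors without H are FALSE.
.hbond_matrix <- function(s, e_cut = -0.5) {
  n <- n_residues(s)
  N <- atom_xyz(s, "N"); H <- atom_xyz(s, "H")
  C <- atom_xyz(s, "C"); O <- atom_xyz(s, "O")
  d2 <- function(a, b) {  # squared distance matrix rows: donor-side atom
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  }
  Hc <- H; Hc[is.na(Hc)] <- 1e6   # donors without H never bond
  E <- 0.084 * 332 * (1 / sqrt(pmax(d2(N, O), 1e-12)) +
                      1 / sqrt(pmax(d2(Hc, C), 1e-12)) -
                      1 / sqrt(pmax(d2(Hc, O), 1e-12)) -
                      1 / sqrt(pmax(d2(N, C), 1e-12)))
  near <- abs(outer(seq_len(n), seq_len(n), "-")) < 2
  bond <- E < e_cut & !near
  bond[is.na(bond)] <- FALSE
  bond
}

#' DSSP-style secondary-structure assignment
#'
#' Assigns per-residue secondary-structure labels from backbone
#' hydrogen-bond patterns following the Kabsch-Sander rules: H (alpha
#' helix) from two consecutive i -> i+4 turns, G (3_10 helix) from 3-turns,
#' I (pi helix) from 5-turns, E/B from parallel and antiparallel bridge
#' patterns, T for isolated turns, C otherwise. Amide hydrogens are placed
#' automatically when absent. Also classifies each residue's (phi, psi)
#' into a Ramachandran region (see [classify_rama_region()]).
#'
#' @param s a [backbone_structure()].
#' @return An object of class `ss_assignment`: a list with `dssp` (character
#'   vector over the alphabet H, G, I, E, B, T, C), `region` (alpha, beta,
#'   ppii, alphaL, other; NA where phi or psi is undefined), `phi`, `psi`,
#'   and the logical hydrogen-bond matrix `hbond`.
#' @examples
#' ss <- assign_dssp(build_from_dihedrals(strrep("A", 12), -57, -47))
#' table(ss$dssp)
#' @export
assign_dssp <- function(s) {
  stopifnot(inherits(s, "backbone_structure"))
  n <- n_residues(s)
  dih <- measure_dihedrals(s)
  region <- rep(NA_character_, n)
  ok <- !is.na(dih$phi) & !is.na(dih$psi)
  region[ok] <- classify_rama_region(dih$phi[ok], dih$psi[ok])
  if (n < 3) {
    return(structure(list(dssp = rep("C", n), region = region,
                          phi = dih$phi, psi = dih$psi,
                          hbond = matrix(FALSE, n, n)),
                     class = "ss_assignment"))
  }
  s <- place_amide_hydrogens(s)
  bond <- .hbond_matrix(s)

  # n-turn at i: CO(i) accepts from NH(i + n)
  turn <- function(k) {
    i <- seq_len(max(n - k, 0))
    i[bond[cbind(i + k, i)]]
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  lab <- rep("C", n)

  # helices from two consecutive n-turns (minimal helix), alpha first
  run_marks <- function(tt, k) {
    m <- rep(FALSE, n)
    for (i in tt[(tt + 1) %in% tt])     # turns at i and i+1
      m[(i + 1):(i + k)] <- TRUE
    m
  }
  is_h <- run_marks(t4, 4)

  # bridges (Kabsch-Sander): i, j non-adjacent
  para <- anti <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) {
    js <- seq_len(n)
    js <- js[abs(js - i) > 2 & js > 1 & js < n]
    for (j in js) {
      if ((bond[j, i - 1] && bond[i + 1, j]) ||
          (bond[i, j - 1] && bond[j + 1, i]))
        para[i, j] <- TRUE
      if ((bond[i, j] && bond[j, i]) ||
          (bond[j + 1, i - 1] && bond[i + 1, j - 1]))
        anti[i, j] <- TRUE
    }
  }
  in_bridge <- apply(para | anti, 1, any)
  # extended strand E when part of a ladder (adjacent residue also bridges),
  # isolated bridge B
  is_e <- in_bridge & !is_h
  lab[is_e] <- "B"
  ladder <- is_e & (c(FALSE, is_e[-n]) | c(is_e[-1], FALSE))
  lab[ladder] <- "E"

  lab[is_h] <- "H"
  is_g <- run_marks(t3, 3) & lab == "C"
  lab[is_g] <- "G"
  is_i <- run_marks(t5, 5) & lab == "C"
  lab[is_i] <- "I"

  # isolated turns
  for (k in c(3, 4, 5)) {
    tt <- turn(k)
    for (i in tt) {
      span <- (i + 1):(i + k - 1)
      span <- span[span <= n]
      lab[span][lab[span] == "C"] <- "T"
    }
  }

  structure(list(dssp = lab, region = region,
                 phi = dih$phi, psi = dih$psi, hbond = bond),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat("<ss_assignment>", paste(x$dssp, collapse = ""), "\n")
  invisible(x)
}

#' Classify a Ramachandran point into a canonical region
#'
#' Assigns (phi, psi) pairs to the canonical secondary-structure regions of
#' the Ramachandran map: alpha helix at (-60, -45), beta sheet at
#' (-135, 135), polyproline II at (-75, 150) and left-handed alpha helix at
#' (+60, +45). A point belongs to a region when it lies within `half_width`
#' degrees of the region centre on both axes (wrap-aware); among qualifying
#' regions the nearest centre (angular Euclidean distance) wins, with ties
#' broken in the fixed order alpha > beta > ppii > alphaL. Points outside
#' every window are labelled "other".
#'
#' @param phi,psi dihedrals in degrees (vectorized).
#' @param half_width half-width of the square region window in degrees
#'   (default 30).
#' @return Character vector of region labels.
#' @export
classify_rama_region <- function(phi, psi, half_width = 30) {
  if (any(!is.finite(phi)) || any(!is.finite(psi)))
    stop("classify_rama_region: non-finite angle")
  centers <- rbind(alpha = c(-60, -45), beta = c(-135, 135),
                   ppii = c(-75, 150), alphaL = c(60, 45))
  out <- character(length(phi))
  dphi <- abs(wrap180(outer(phi, centers[, 1], "-")))
  dpsi <- abs(wrap180(outer(psi, centers[, 2], "-")))
  inside <- dphi <= half_width & dpsi <= half_width
  dist2 <- dphi^2 + dpsi^2
  dist2[!inside] <- Inf
  for (i in seq_along(phi)) {
    if (!any(inside[i, ])) { out[i] <- "other"; next }
    out[i] <- rownames(centers)[which.min(dist2[i, ])]  # ties: fixed order
  }
  out
}
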