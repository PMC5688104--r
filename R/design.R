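# Binding thermodynamics (Kd <-> free energy) and the rule-based redesign
# of the 12/1 peptide toward higher helical propensity, with anchor-residue
# conservation checks.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal / (mol K)

#' Convert a dissociation constant to a binding free energy
#'
#' `dG = R T ln(Kd)` with Kd in molar, R = 1.987e-3 kcal/(mol K). The
#' default temperature of 293 K is the one at which the conversion
#' reproduces the ITC-derived free energies of the five MDM2-binding
#' peptides tabulated in [mdm2_binding_table()].
#'
#' @param kd_nM dissociation constant in nM (> 0; vectorized).
#' @param temperature_K temperature in K (default 293).
#' @return Binding free energy in kcal/mol (negative for sub-molar Kd).
#' @examples
#' kd_to_dg(1543.2)   # p53 wild type: about -7.79 kcal/mol
#' @export
kd_to_dg <- function(kd_nM, temperature_K = 293) {
  if (any(!is.finite(kd_nM) | kd_nM <= 0))
    stop("kd_to_dg: Kd must be positive")
  GAS_CONSTANT_KCAL * temperature_K * log(kd_nM * 1e-9)
}

#' @rdname kd_to_dg
#' @param dg_kcal_mol binding free energy in kcal/mol.
#' @export
dg_to_kd <- function(dg_kcal_mol, temperature_K = 293) {
  exp(dg_kcal_mol / (GAS_CONSTANT_KCAL * temperature_K)) * 1e9
}

#' Reference table of MDM2-binding peptides
#'
#' The five p53/12-1 peptides with their ITC dissociation constants and
#' binding free energies, as shipped in `extdata/mdm2_binding.tsv`. The
#' anchor triad (Phe, Trp, Leu at offsets 4, 8, 11 of the 12-mers) is
#' conserved across all rows.
#'
#' @return A data frame with columns `name`, `sequence`, `kd_nM`,
#'   `kd_err_nM`, `dg_kcal_mol`, `dg_err_kcal_mol`.
#' @export
mdm2_binding_table <- function() {
  utils::read.delim(system.file("extdata", "mdm2_binding.tsv",
                                package = "pepscape", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Check conservation of the anchor-residue triad
#'
#' Verifies that each sequence carries the expected anchor residues (by
#' default the Phe/Trp/Leu triad at offsets 4, 8 and 11, the residues
#' buried in the MDM2 hydrophobic groove).
#'
#' @param seqs a list of [peptide_sequence()] objects (or strings), or a
#'   single sequence.
#' @param offsets 1-based anchor positions (default `c(4, 8, 11)`).
#' @param expected expected one-letter codes (default `c("F", "W", "L")`).
#' @return A list with `conserved` (named logical, one per sequence) and
#'   `all_conserved`.
#' @export
check_anchor_conservation <- function(seqs, offsets = c(4, 8, 11),
                                      expected = c("F", "W", "L")) {
  if (!is.list(seqs)) seqs <- list(seqs)
  seqs <- lapply(seqs, as_peptide_sequence)
  if (length(offsets) != length(expected))
    stop("check_anchor_conservation: offsets and expected lengths differ")
  res <- vapply(seqs, function(s) {
    if (length(s) < max(offsets))
      stop("check_anchor_conservation: sequence ", seq_name(s),
           " shorter than anchor offset ", max(offsets))
    all(unclass(s)[offsets] == expected)
  }, TRUE)
  names(res) <- vapply(seqs, seq_name, "")
  list(conserved = res, all_conserved = all(res))
}

## ---- design rules --------------------------------------------------------

#' Create a peptide design rule
#'
#' A transformation applied to a peptide sequence during redesign: deletion
#' of a position or substitution of a position by one of a set of residues.
#'
#' @param id short rule identifier.
#' @param description free-text rationale.
#' @param type `"delete"` or `"substitute"`.
#' @param position 1-based position in the input sequence.
#' @param to candidate replacement residues (substitution rules only).
#' @return An object of class `design_rule`.
#' @export
design_rule <- function(id, description, type = c("substitute", "delete"),
                        position, to = NULL) {
  type <- match.arg(type)
  if (type == "substitute" && !length(to))
    stop("design_rule: substitution rule needs candidate residues")
  structure(list(id = id, description = description, type = type,
                 position = as.integer(position),
                 to = if (is.null(to)) NULL else toupper(to)),
            class = "design_rule")
}

#' The standard 12/1 redesign rule set
#'
#' The four-rule redesign of the 12/1 peptide (MPRFMDYWEGLN): (i) replace
#' the helix-breaking Pro2 with Thr; (ii) delete the dispensable Met1;
#' (iii) replace Met5, which favours a left-handed helical conformation
#' and oxidizes readily, with Ala; (iv) replace the beta-prone Tyr7 and
#' Gly10 with Leu, the strongest helix former after Ala and Arg among the
#' substitutions compatible with the binding interface. Applied together
#' the rules yield the single candidate TRFADLWELLN ("12/1m").
#'
#' @return A list of [design_rule()] objects.
#' @export
design_rules_12_1 <- function() {
  list(
    design_rule("P2T", "Pro disrupts the helix; replace by Thr",
                "substitute", 2, "T"),
    design_rule("delM1", "N-terminal Met dispensable for binding",
                "delete", 1),
    design_rule("M5A", "Met5 favours a left-handed conformation; Ala",
                "substitute", 5, "A"),
    design_rule("Y7L", "beta-prone Tyr7 to helix-favouring Leu",
                "substitute", 7, "L"),
    design_rule("G10L", "helix-indifferent Gly10 to Leu",
                "substitute", 10, "L"))
}

#' Apply design rules to a peptide
#'
#' Generates candidate redesigns as the cross-product of the allowed
#' substitutions at each rule position, with any deletion rules applied to
#' every candidate. Anchor positions (default 4, 8, 11: Phe, Trp, Leu) and
#' charged positions (default 3, 6, 9 for 12/1: Arg, Asp, Glu) are locked;
#' a rule targeting them is an error. Candidates are scored with
#' [propensity_score()] and returned in deterministic order (substitution
#' options enumerated position by position).
#'
#' @param seq input [peptide_sequence()] (default the 12/1 peptide).
#' @param rules list of [design_rule()] (default [design_rules_12_1()]).
#' @param locked_positions positions that must not be substituted or
#'   deleted (default anchors `c(4, 8, 11)` plus charged `c(3, 6, 9)`).
#' @param scale propensity scale for scoring (see [helix_propensity_scale()]).
#' @return A list of `design_proposal` objects: each has `sequence` (a
#'   [peptide_sequence()]), `applied_rules` and `propensity`.
#' @examples
#' props <- apply_design_rules()
#' as.character(props[[1]]$sequence)   # "TRFADLWELLN"
#' @export
apply_design_rules <- function(seq = peptide_sequence("MPRFMDYWEGLN",
                                                      name = "12/1"),
                               rules = design_rules_12_1(),
                               locked_positions = c(4, 8, 11, 3, 6, 9),
                               scale = helix_propensity_scale()) {
  seq <- as_peptide_sequence(seq)
  n <- length(seq)
  for (r in rules) {
    if (!inherits(r, "design_rule")) stop("apply_design_rules: not a rule")
    if (r$position < 1 || r$position > n)
      stop("apply_design_rules: rule ", r$id, " targets position ",
           r$position, " outside the sequence")
    if (r$position %in% locked_positions)
      stop("apply_design_rules: rule ", r$id,
           " targets locked position ", r$position,
           " (anchor or charged residue)")
  }
  subs <- Filter(function(r) r$type == "substitute", rules)
  dels <- Filter(function(r) r$type == "delete", rules)
  del_pos <- vapply(dels, `[[`, 0L, "position")

  # cross-product of substitution options, first rule varying slowest
  grids <- lapply(subs, function(r) seq_along(r$to))
  combos <- if (length(grids)) {
    do.call(expand.grid, rev(grids))[, rev(seq_along(grids)), drop = FALSE]
  } else data.frame(row.names = 1)
  out <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    res <- unclass(seq)
    applied <- character(0)
    for (j in seq_along(subs)) {
      r <- subs[[j]]
      res[r$position] <- r$to[combos[k, j]]
      applied <- c(applied, sprintf("%s:%s%d%s", r$id, seq[r$position],
                                    r$position, res[r$position]))
    }
    if (length(del_pos)) {
      applied <- c(applied, vapply(dels, function(r)
        sprintf("%s:del%s%d", r$id, seq[r$position], r$position), ""))
      res <- res[-del_pos]
    }
    cand <- peptide_sequence(res, name = sprintf("%s-design%d",
                                                 seq_name(seq), k))
    out[[k]] <- structure(
      list(sequence = cand, applied_rules = applied,
           propensity = propensity_score(cand, scale)),
      class = "design_proposal")
  }
  out
}

#' @export
print.design_proposal <- function(x, ...) {
  cat(sprintf("<design_proposal> %s (propensity %.3f)\n  rules: %s\n",
              as.character(x$sequence), x$propensity,
              paste(x$applied_rules, collapse = ", ")))
  invisible(x)
}

## ---- helix propensity ----------------------------------------------------

#' Per-residue helix propensity scale
#'
#' Loads a helix-propensity table (default: the Pace-Scholtz free-energy
#' costs relative to alanine shipped in `extdata/helix_propensity.tsv`) and
#' returns propensities as `-ddG` so that higher values mean more helical.
#' On this scale alanine ranks first and arginine and leucine share the
#' next rank, with glycine and proline at the bottom.
#'
#' @param path optional TSV with columns `residue`, `ddg_kcal_mol`.
#' @return Named numeric vector of propensities (kcal/mol, higher = more
#'   helical), one entry per residue code in the table.
#' @export
helix_propensity_scale <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "helix_propensity.tsv",
                        package = "pepscape", mustWork = TRUE)
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("residue", "ddg_kcal_mol") %in% names(tb)))
    stop("helix_propensity_scale: columns residue, ddg_kcal_mol required")
  stats::setNames(-tb$ddg_kcal_mol, toupper(tb$residue))
}

#' Mean helix propensity of a sequence
#'
#' Mean per-residue propensity under a helix-propensity scale; higher
#' scores indicate sequences more predisposed to form an alpha helix.
#' Used to rank design candidates (the redesigned TRFADLWELLN scores above
#' the parent MPRFMDYWEGLN).
#'
#' @param seq a [peptide_sequence()] (or string).
#' @param scale named propensity vector (see [helix_propensity_scale()]).
#' @return Mean propensity (scale units).
#' @export
propensity_score <- function(seq, scale = helix_propensity_scale()) {
  seq <- as_peptide_sequence(seq)
  missing <- setdiff(unique(unclass(seq)), names(scale))
  if (length(missing))
    stop("propensity_score: residues missing from scale: ",
         paste(missing, collapse = ", "))
  mean(scale[unclass(seq)])
}
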