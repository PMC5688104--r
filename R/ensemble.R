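# Ordered collections of conformations of one peptide, with per-frame
# cached metrics (CA RMSD to a reference in nm, Rg in nm, DSSP string).

#' Construct a peptide ensemble
#'
#' An ensemble is an ordered collection of [backbone_structure()]
#' conformations ("frames") of a single sequence, the in-memory analogue of
#' the lambda = 0 replica of a replica-exchange trajectory. Per-frame
#' metrics are attached by [annotate_ensemble()].
#'
#' @param frames list of [backbone_structure()] objects sharing one sequence.
#' @param weights optional non-negative per-frame weights (sum > 0).
#' @return An object of class `peptide_ensemble` with elements `sequence`,
#'   `frames`, `weights` and (after annotation) `meta`.
#' @export
peptide_ensemble <- function(frames, weights = NULL) {
  if (!length(frames)) stop("peptide_ensemble: no frames")
  seqs <- vapply(frames, function(f) as.character(f$sequence), "")
  if (length(unique(seqs)) != 1L)
    stop("peptide_ensemble: frames carry different sequences")
  if (!is.null(weights)) {
    if (length(weights) != length(frames) || any(weights < 0) ||
        sum(weights) <= 0)
      stop("peptide_ensemble: invalid weights")
  }
  structure(list(sequence = frames[[1]]$sequence, frames = frames,
                 weights = weights, meta = NULL),
            class = "peptide_ensemble")
}

#' @export
print.peptide_ensemble <- function(x, ...) {
  cat(sprintf("<peptide_ensemble> %s: %d frames of %d residues%s\n",
              seq_name(x$sequence), length(x$frames), length(x$sequence),
              if (is.null(x$meta)) "" else " (annotated)"))
  invisible(x)
}

#' @export
length.peptide_ensemble <- function(x) length(x$frames)

#' Attach per-frame metrics to an ensemble
#'
#' Computes, for every frame, the CA superposition RMSD to a reference
#' conformation (nm), the radius of gyration (nm) and the DSSP string, and
#' caches them in `e$meta` (a data frame with one row per frame).
#'
#' @param e a [peptide_ensemble()].
#' @param reference a [backbone_structure()] with the same residue count
#'   (conventionally the receptor-bound conformation); if `NULL` the RMSD
#'   column is `NA`.
#' @return The annotated ensemble.
#' @export
annotate_ensemble <- function(e, reference = NULL) {
  stopifnot(inherits(e, "peptide_ensemble"))
  nf <- length(e$frames)
  rmsd <- rep(NA_real_, nf)
  rg <- numeric(nf)
  ss <- character(nf)
  for (i in seq_len(nf)) {
    f <- e$frames[[i]]
    if (!is.null(reference)) rmsd[i] <- kabsch_rmsd(f, reference) / 10
    rg[i] <- radius_of_gyration(f) / 10
    ss[i] <- paste(assign_dssp(f)$dssp, collapse = "")
  }
  e$meta <- data.frame(frame = seq_len(nf), rmsd_nm = rmsd, rg_nm = rg,
                       ss = ss, stringsAsFactors = FALSE)
  e
}
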