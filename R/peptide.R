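#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Create a peptide sequence
#'
#' A `peptide_sequence` is an ordered vector of one-letter amino-acid codes
#' with a short label, the elementary description of every peptide handled by
#' the package (e.g. the p53 transactivation peptide `QETFSDLWKLLP` or the
#' phage-derived 12/1 peptide `MPRFMDYWEGLN`).
#'
#' @param residues character; either a single string of one-letter codes
#'   (`"QETFSDLWKLLP"`) or a character vector with one code per residue.
#' @param name short label for the peptide (default `"peptide"`).
#' @return An object of class `peptide_sequence`: a character vector of
#'   one-letter codes with attribute `name`.
#' @examples
#' p53 <- peptide_sequence("QETFSDLWKLLP", name = "p53-WT")
#' length(p53)
#' @export
peptide_sequence <- function(residues, name = "peptide") {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) == 0L)
    stop("peptide_sequence: sequence must be non-empty")
  bad <- setdiff(unique(residues), AA1)
  if (length(bad))
    stop("peptide_sequence: unknown residue code(s): ",
         paste(bad, collapse = ", "))
  structure(residues, name = as.character(name)[1],
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s (%d aa)\n  %s\n",
              attr(x, "name"), length(x), paste(x, collapse = "")))
  invisible(x)
}

#' @rdname peptide_sequence
#' @param x an object to coerce.
#' @export
as_peptide_sequence <- function(x, name = NULL) {
  if (inherits(x, "peptide_sequence")) {
    if (!is.null(name)) attr(x, "name") <- name
    return(x)
  }
  peptide_sequence(x, name = if (is.null(name)) "peptide" else name)
}

#' @export
as.character.peptide_sequence <- function(x, ...) {
  paste(unclass(x), collapse = "")
}

seq_name <- function(x) attr(x, "name")
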