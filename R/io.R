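# File formats: multi-model PDB ensembles, FASTA sequences, pulling TSV,
# JSON/TSV result files and YAML run configuration.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA3_TO_1 <- stats::setNames(names(AA3), AA3)

.pdb_atom_field <- function(name) {
  # backbone atom names occupy columns 13-16; single-letter elements are
  # right-padded from column 14 per PDB convention
  if (nchar(name) < 4) sprintf(" %-3s", name) else name
}

#' Write an ensemble as a multi-model PDB file
#'
#' Writes each frame as one MODEL/ENDMDL block with standard ATOM records
#' (coordinates in Angstrom, 1-based residue numbering offset by
#' `first_resno - 1`).
#'
#' @param e a [peptide_ensemble()] or a single [backbone_structure()].
#' @param path output file path.
#' @param first_resno residue number given to the first residue (default 1;
#'   p53 peptides are conventionally numbered from 16).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(e, path, first_resno = 1L) {
  if (inherits(e, "backbone_structure")) e <- peptide_ensemble(list(e))
  stopifnot(inherits(e, "peptide_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  res3 <- AA3[unclass(e$sequence)]
  for (m in seq_along(e$frames)) {
    f <- e$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    ord <- order(f$resno, match(f$atom, c("N", "H", "CA", "C", "O")))
    lines <- sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_along(ord),
      vapply(f$atom[ord], .pdb_atom_field, ""),
      res3[f$resno[ord]],
      f$resno[ord] + first_resno - 1L,
      f$coords[ord, 1], f$coords[ord, 2], f$coords[ord, 3],
      1, 0,
      substr(f$atom[ord], 1, 1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL-delimited ATOM records into a [peptide_ensemble()].
#' Only backbone atoms (N, CA, C, O, amide H) are retained. All models must
#' share one sequence; each model must provide N, CA, C and O for every
#' residue.
#'
#' @param path PDB file path.
#' @return A [peptide_ensemble()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("read_multimodel_pdb: no such file: ", path)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("read_multimodel_pdb: no ATOM records in ", path)
  # implicit single model when no MODEL records present
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  open_at <- which(is_model)
  if (length(open_at) > sum(is_end))
    stop("read_multimodel_pdb: unterminated MODEL block (missing ENDMDL), ",
         "opened at line ", open_at[sum(is_end) + 1L])
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  frames <- list()
  seq1 <- NULL
  for (m in sort(unique(atom_model))) {
    al <- atom_lines[atom_model == m]
    name <- trimws(substr(al, 13, 16))
    resnam <- trimws(substr(al, 18, 20))
    resno <- as.integer(substr(al, 23, 26))
    x <- as.numeric(substr(al, 31, 38))
    y <- as.numeric(substr(al, 39, 46))
    z <- as.numeric(substr(al, 47, 54))
    keep <- name %in% c("N", "CA", "C", "O", "H")
    name <- name[keep]; resnam <- resnam[keep]; resno <- resno[keep]
    xyz <- cbind(x[keep], y[keep], z[keep])
    resno <- resno - min(resno) + 1L
    aa <- AA3_TO_1[resnam[match(seq_len(max(resno)), resno)]]
    if (anyNA(aa))
      stop("read_multimodel_pdb: model ", m, ": unknown or missing residue")
    sq <- paste(aa, collapse = "")
    if (is.null(seq1)) seq1 <- sq
    else if (sq != seq1)
      stop("read_multimodel_pdb: model ", m,
           ": sequence differs from model 1")
    f <- try(backbone_structure(
      peptide_sequence(sq, name = sub("\\.pdb$", "", basename(path))),
      xyz, name, resno), silent = TRUE)
    if (inherits(f, "try-error"))
      stop("read_multimodel_pdb: model ", m, ": ",
           attr(f, "condition")$message)
    frames[[length(frames) + 1L]] <- f
  }
  peptide_ensemble(frames)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A list of [peptide_sequence()] objects named by FASTA headers.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("read_fasta_sequences: no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("read_fasta_sequences: no FASTA headers in ", path)
  id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  stats::setNames(
    lapply(seq_along(seqs),
           function(i) peptide_sequence(seqs[[i]], name = names[i])),
    names)
}

#' Read a table of binding constants
#'
#' Reads a TSV with columns `name`, `kd_nM` and optionally `kd_err`.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_kd_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "kd_nM")
  if (!all(need %in% names(tb)))
    stop("read_kd_table: required columns: ", paste(need, collapse = ", "))
  tb
}

#' Read a pulling-trajectory table
#'
#' Reads the TSV dialect with columns `replicate`, `frame`,
#' `com_distance_nm`, `helical_count` and returns a [pull_replicate_set()].
#'
#' @param path TSV file path.
#' @param peptide peptide name (default from the file name).
#' @param n_residues residue count of the pulled peptide (default: maximum
#'   observed helical count).
#' @return A [pull_replicate_set()].
#' @export
read_pulling_tsv <- function(path, peptide = NULL, n_residues = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicate", "frame", "com_distance_nm", "helical_count")
  if (!all(need %in% names(tb)))
    stop("read_pulling_tsv: required columns: ", paste(need, collapse = ", "))
  if (is.null(peptide)) peptide <- sub("\\.tsv$", "", basename(path))
  if (is.null(n_residues)) n_residues <- max(tb$helical_count)
  reps <- lapply(split(tb, tb$replicate), function(d) {
    d <- d[order(d$frame), ]
    data.frame(frame = d$frame, com_distance_nm = d$com_distance_nm,
               helical_count = d$helical_count)
  })
  pull_replicate_set(reps, peptide = peptide, n_residues = n_residues)
}

#' Write a pulling replicate set as TSV
#'
#' @param p a [pull_replicate_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pulling_tsv <- function(p, path) {
  stopifnot(inherits(p, "pull_replicate_set"))
  rows <- do.call(rbind, lapply(seq_along(p$replicates), function(i) {
    d <- p$replicates[[i]]
    cbind(replicate = i, d)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Reads a YAML configuration holding input paths, analysis toggles, bin
#' widths, the analysis thresholds (70% helicity, 2 A ideal-helix RMSD,
#' 2.8 A hydrogen-bond cutoff, 50% retention at 1.8 nm) and seeds, merged
#' over package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = ".",
    bin_width_rama_deg = 10,
    bin_width_rmsd_nm = 0.05,
    bin_width_rg_nm = 0.05,
    helical_frame_fraction = 0.70,
    ideal_rmsd_cut_A = 2.0,
    hbond_cutoff_A = 2.8,
    retention_fraction = 0.5,
    start_distance_nm = 1.33,
    probe_distance_nm = 1.8,
    stages = list(metrics = TRUE, fes = TRUE, hbonds = TRUE,
                  pulling = TRUE, design = TRUE))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  num <- unlist(cfg[c("bin_width_rama_deg", "bin_width_rmsd_nm",
                      "bin_width_rg_nm", "ideal_rmsd_cut_A",
                      "hbond_cutoff_A", "retention_fraction")])
  if (any(num <= 0)) stop("read_run_config: thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Write analysis outputs to a directory
#'
#' Writes the deterministic file set for one analysis run: `metrics.json`
#' (the three helicity statistics), `fes_rama.tsv` / `fes_rmsd_rg.tsv` plus
#' `clusters.json`, `hbonds.tsv`, `pull_profile.tsv` with
#' `pull_classification.json`, `design_report.json`, and `run_log.json`
#' recording version, seed and thresholds. Stages toggled off in the
#' configuration produce no files.
#'
#' @param results named list with any of `metrics`, `fes_rama`,
#'   `fes_rmsd_rg`, `clusters`, `hbonds`, `profile`, `classification`,
#'   `design`.
#' @param config a [read_run_config()] list.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, config = read_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)
  w_json <- function(x, f) {
    jsonlite::write_json(x, out(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, out(f))
  }
  st <- config$stages
  if (isTRUE(st$metrics) && !is.null(results$metrics))
    w_json(unclass(results$metrics), "metrics.json")
  if (isTRUE(st$fes)) {
    if (!is.null(results$fes_rama)) {
      write_fes_tsv(results$fes_rama, out("fes_rama.tsv"))
      written <- c(written, out("fes_rama.tsv"))
    }
    if (!is.null(results$fes_rmsd_rg)) {
      write_fes_tsv(results$fes_rmsd_rg, out("fes_rmsd_rg.tsv"))
      written <- c(written, out("fes_rmsd_rg.tsv"))
    }
    if (!is.null(results$clusters))
      w_json(lapply(results$clusters, unclass), "clusters.json")
  }
  if (isTRUE(st$hbonds) && !is.null(results$hbonds)) {
    utils::write.table(results$hbonds, out("hbonds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, out("hbonds.tsv"))
  }
  if (isTRUE(st$pulling)) {
    if (!is.null(results$profile)) {
      utils::write.table(as.data.frame(unclass(results$profile)[
        c("index", "mean_com_distance_nm", "mean_helical_count",
          "jackknife_se")]),
        out("pull_profile.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      written <- c(written, out("pull_profile.tsv"))
    }
    if (!is.null(results$classification))
      w_json(results$classification, "pull_classification.json")
  }
  if (isTRUE(st$design) && !is.null(results$design))
    w_json(results$design, "design_report.json")
  w_json(list(package = "pepscape",
              version = as.character(utils::packageVersion("pepscape")),
              seed = config$seed,
              thresholds = config[c("helical_frame_fraction",
                                    "ideal_rmsd_cut_A", "hbond_cutoff_A",
                                    "retention_fraction",
                                    "probe_distance_nm")]),
         "run_log.json")
  invisible(written)
}

#' Write a free-energy surface as TSV
#'
#' One row per grid cell: bin centres, the -ln(population) value and the
#' empty-bin mask.
#'
#' @param f a [fes2d()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fes_tsv <- function(f, path) {
  stopifnot(inherits(f, "fes2d"))
  xc <- (f$x_edges[-1] + f$x_edges[-length(f$x_edges)]) / 2
  yc <- (f$y_edges[-1] + f$y_edges[-length(f$y_edges)]) / 2
  g <- expand.grid(x = xc, y = yc)
  g$value <- as.vector(f$values)
  g$masked <- as.vector(f$mask)
  names(g)[1:2] <- c(f$x_name, f$y_name)
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
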