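# Ensemble-level statistics: the three helicity metrics, 2D free-energy
# surfaces (-ln population) over Ramachandran or (RMSD, Rg) coordinates,
# watershed basin extraction, and backbone hydrogen-bond occupancy.

#' Three helicity statistics of an ensemble
#'
#' Computes the three standard helicity metrics of a peptide ensemble:
#' (i) the mean percentage of residues in an alpha-helical (DSSP H)
#' conformation; (ii) the percentage of frames in which at least 70% of
#' residues are helical; (iii) the percentage of frames within 2 A CA RMSD
#' of an ideal helix reference built at (-57, -47).
#'
#' Only DSSP label H counts as helical; 3_10 (G) and pi (I) helices are
#' tabulated separately by [assign_dssp()].
#'
#' @param e an annotated [peptide_ensemble()] (see [annotate_ensemble()]);
#'   an unannotated ensemble is annotated on the fly.
#' @param ideal_ref ideal-helix reference [backbone_structure()]; default is
#'   built from the ensemble's sequence at (-57, -47).
#' @param frame_fraction frame-level helicity threshold for metric ii
#'   (default 0.70).
#' @param rmsd_cut_A CA RMSD cutoff for metric iii in Angstrom (default 2).
#' @return A list of class `helicity_metrics` with `pct_residues_alpha`,
#'   `pct_frames_ge70` and `pct_frames_within_2A`, each in \[0, 100\].
#' @export
compute_helicity_metrics <- function(e, ideal_ref = NULL,
                                     frame_fraction = 0.70,
                                     rmsd_cut_A = 2.0) {
  stopifnot(inherits(e, "peptide_ensemble"))
  if (!length(e$frames)) stop("compute_helicity_metrics: empty ensemble")
  if (is.null(ideal_ref))
    ideal_ref <- build_from_dihedrals(e$sequence, -57, -47)
  if (length(ideal_ref$sequence) != length(e$sequence))
    stop("compute_helicity_metrics: reference length mismatch")
  if (is.null(e$meta)) e <- annotate_ensemble(e)
  n <- length(e$sequence)
  hfrac <- vapply(strsplit(e$meta$ss, ""),
                  function(x) mean(x == "H"), 0)
  rmsd <- vapply(e$frames, kabsch_rmsd, 0, b = ideal_ref)
  structure(list(
    pct_residues_alpha = 100 * mean(hfrac),
    pct_frames_ge70 = 100 * mean(hfrac >= frame_fraction),
    pct_frames_within_2A = 100 * mean(rmsd < rmsd_cut_A)),
    class = "helicity_metrics")
}

#' @export
print.helicity_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<helicity_metrics>\n",
    "  residues alpha-helical (DSSP H): %6.2f %%\n",
    "  frames >= 70%% helical:           %6.2f %%\n",
    "  frames < 2 A RMSD of ideal:      %6.2f %%\n"),
    x$pct_residues_alpha, x$pct_frames_ge70, x$pct_frames_within_2A))
  invisible(x)
}

## ---- FES construction ----------------------------------------------------

#' Two-dimensional free-energy surface from scattered points
#'
#' Bins (x, y) points on a regular grid and converts counts to relative
#' free energies `-ln(count / max count)`, so the global minimum sits at 0
#' and empty bins are masked rather than given pseudo-counts.
#'
#' @param x,y coordinates of the sampled points.
#' @param x_edges,y_edges strictly increasing bin edges covering the data.
#' @param x_name,y_name axis names (with units) used in output files.
#' @return An object of class `fes2d`: list with `x_edges`, `y_edges`,
#'   `values` (matrix, `-ln` population, `NA` on masked bins), `mask`
#'   (TRUE = empty), `counts`, and the binned point indices `px`, `py`.
#' @export
fes2d <- function(x, y, x_edges, y_edges, x_name = "x", y_name = "y") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("fes2d: no finite points")
  if (min(x) < min(x_edges) || max(x) > max(x_edges) ||
      min(y) < min(y_edges) || max(y) > max(y_edges))
    stop("fes2d: points outside the binning range")
  px <- findInterval(x, x_edges, rightmost.closed = TRUE,
                     left.open = TRUE)
  px[px == 0L] <- 1L
  py <- findInterval(y, y_edges, rightmost.closed = TRUE,
                     left.open = TRUE)
  py[py == 0L] <- 1L
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(px, levels = seq_len(nx)),
               factor(py, levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  mask <- counts == 0L
  values <- matrix(NA_real_, nx, ny)
  values[!mask] <- -log(counts[!mask] / max(counts))
  structure(list(x_edges = x_edges, y_edges = y_edges, values = values,
                 mask = mask, counts = counts, px = px, py = py,
                 x_name = x_name, y_name = y_name),
            class = "fes2d")
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf(
    "<fes2d> %s x %s: %d x %d bins, %d points, max -ln(pop) %.2f\n",
    x$x_name, x$y_name, nrow(x$values), ncol(x$values), length(x$px),
    max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Ramachandran free-energy surface of an ensemble
#'
#' Pools all residues' defined (phi, psi) pairs across frames and bins them
#' over (-180, 180\]^2, returning the `-ln(population)` surface on which
#' alpha-helical conformations cluster near (-60, -45), beta near
#' (-135, 135) and polyproline II near (-75, 150).
#'
#' @param e a [peptide_ensemble()].
#' @param bin_width bin width in degrees; must divide 360 (default 10).
#' @return A [fes2d()] with axes `phi_deg`, `psi_deg`.
#' @export
ramachandran_fes <- function(e, bin_width = 10) {
  stopifnot(inherits(e, "peptide_ensemble"))
  if (360 %% bin_width != 0)
    stop("ramachandran_fes: bin_width must divide 360")
  phi <- psi <- list()
  for (i in seq_along(e$frames)) {
    d <- measure_dihedrals(e$frames[[i]])
    ok <- !is.na(d$phi) & !is.na(d$psi)
    phi[[i]] <- d$phi[ok]; psi[[i]] <- d$psi[ok]
  }
  phi <- unlist(phi); psi <- unlist(psi)
  if (!length(phi)) stop("ramachandran_fes: no defined (phi, psi) pairs")
  edges <- seq(-180, 180, by = bin_width)
  fes2d(phi, psi, edges, edges, x_name = "phi_deg", y_name = "psi_deg")
}

#' (RMSD, Rg) free-energy surface of an ensemble
#'
#' Per-frame CA superposition RMSD to a reference conformation and radius
#' of gyration (both in nm) binned into a `-ln(population)` surface; the
#' surface whose basins are read as conformational clusters.
#'
#' @param e a [peptide_ensemble()].
#' @param reference reference [backbone_structure()] (conventionally the
#'   receptor-bound helical conformation).
#' @param bin_width_nm bin widths, recycled to (RMSD, Rg) (default 0.05 nm).
#' @return A [fes2d()] with axes `rmsd_nm`, `rg_nm`.
#' @export
rmsd_rg_fes <- function(e, reference, bin_width_nm = c(0.05, 0.05)) {
  stopifnot(inherits(e, "peptide_ensemble"))
  bin_width_nm <- rep(bin_width_nm, length.out = 2)
  if (is.null(e$meta) || all(is.na(e$meta$rmsd_nm)))
    e <- annotate_ensemble(e, reference)
  x <- e$meta$rmsd_nm; y <- e$meta$rg_nm
  ex <- .cover_edges(x, bin_width_nm[1])
  ey <- .cover_edges(y, bin_width_nm[2])
  fes2d(x, y, ex, ey, x_name = "rmsd_nm", y_name = "rg_nm")
}

# grid edges at integer multiples of the bin width covering the data
.cover_edges <- function(v, w) {
  lo <- floor(min(v) / w) * w
  hi <- ceiling(max(v) / w) * w
  if (hi <= lo) hi <- lo + w
  seq(lo, hi, by = w)
}

## ---- basin extraction ----------------------------------------------------

#' Extract basins (clusters) from a free-energy surface
#'
#' Identifies the basins of a [fes2d()] surface and reports them as
#' conformational clusters. Every unmasked cell is assigned to a local
#' minimum by steepest descent over the 8-neighbourhood; shallow minima are
#' then merged into their deeper neighbours until every remaining basin has
#' a persistence (saddle value minus basin minimum) of at least
#' `depth_cut`, and basins holding fewer than `min_pop_pct` percent of the
#' points are discarded (their population is not reassigned, so reported
#' populations sum to at most 100%).
#'
#' @param f a [fes2d()].
#' @param depth_cut minimum basin persistence in `-ln(population)` units
#'   (default 1.0).
#' @param min_pop_pct discard basins below this population percentage
#'   (default 1.0).
#' @return A list of `fes_cluster` objects, sorted by decreasing
#'   population; each has `centre` (x, y of the basin minimum),
#'   `centroid` (population-weighted mean of member points), `population`
#'   (percent of all points), `min_value` and `representative_point`
#'   (index of the point nearest the basin centroid, in bin-width units).
#' @export
extract_basins <- function(f, depth_cut = 1.0, min_pop_pct = 1.0) {
  stopifnot(inherits(f, "fes2d"))
  v <- f$values
  nx <- nrow(v); ny <- ncol(v)
  if (all(f$mask)) stop("extract_basins: all bins are masked")
  cells <- which(!f$mask)
  ord <- cells[order(v[cells])]

  # steepest-descent assignment: process cells by increasing value; a cell
  # joins the basin of its lowest-valued lower neighbour, or seeds a new one
  basin <- matrix(0L, nx, ny)
  minima <- integer(0)
  for (c0 in ord) {
    i <- (c0 - 1L) %% nx + 1L
    j <- (c0 - 1L) %/% nx + 1L
    ii <- max(1, i - 1):min(nx, i + 1)
    jj <- max(1, j - 1):min(ny, j + 1)
    nb <- as.vector(outer(ii, (jj - 1L) * nx, "+"))
    nb <- nb[nb != c0]
    nbv <- v[nb]
    lower <- nb[!is.na(nbv) & nbv < v[c0]]
    if (!length(lower)) {
      minima <- c(minima, c0)
      basin[c0] <- length(minima)
    } else {
      basin[c0] <- basin[lower[which.min(v[lower])]]
    }
  }

  # persistence merging: saddle height between adjacent basins
  repeat {
    k <- length(minima)
    if (k <= 1) break
    # lowest boundary value between each pair of adjacent basins
    saddle <- matrix(Inf, k, k)
    for (c0 in cells) {
      i <- (c0 - 1L) %% nx + 1L
      j <- (c0 - 1L) %/% nx + 1L
      ii <- max(1, i - 1):min(nx, i + 1)
      jj <- max(1, j - 1):min(ny, j + 1)
      nb <- as.vector(outer(ii, (jj - 1L) * nx, "+"))
      nb <- nb[nb != c0 & basin[nb] != 0L & basin[nb] != basin[c0]]
      for (c1 in nb) {
        h <- max(v[c0], v[c1])
        a <- basin[c0]; b <- basin[c1]
        if (h < saddle[a, b]) saddle[a, b] <- saddle[b, a] <- h
      }
    }
    pers <- rep(Inf, k)
    mergeto <- rep(NA_integer_, k)
    for (a in seq_len(k)) {
      adj <- which(is.finite(saddle[a, ]))
      if (!length(adj)) next
      p <- saddle[a, adj] - v[minima[a]]
      deeper <- adj[v[minima[adj]] < v[minima[a]]]
      if (!length(deeper)) next
      pers[a] <- min(saddle[a, deeper] - v[minima[a]])
      mergeto[a] <- deeper[which.min(saddle[a, deeper])]
    }
    worst <- which.min(pers)
    if (!is.finite(pers[worst]) || pers[worst] >= depth_cut) break
    basin[basin == worst] <- mergeto[worst]
    basin[basin > worst] <- basin[basin > worst] - 1L
    minima <- minima[-worst]
  }

  # per-point basin membership
  pt_cell <- f$px + (f$py - 1L) * nx
  pt_basin <- basin[pt_cell]
  npts <- length(f$px)
  xc <- (f$x_edges[-1] + f$x_edges[-length(f$x_edges)]) / 2
  yc <- (f$y_edges[-1] + f$y_edges[-length(f$y_edges)]) / 2
  wx <- diff(f$x_edges)[1]; wy <- diff(f$y_edges)[1]

  clusters <- list()
  for (b in seq_along(minima)) {
    members <- which(pt_basin == b)
    pop <- 100 * length(members) / npts
    if (pop < min_pop_pct) next
    c0 <- minima[b]
    i <- (c0 - 1L) %% nx + 1L
    j <- (c0 - 1L) %/% nx + 1L
    cx <- mean(xc[f$px[members]]); cy <- mean(yc[f$py[members]])
    d2 <- ((xc[f$px[members]] - cx) / wx)^2 +
          ((yc[f$py[members]] - cy) / wy)^2
    clusters[[length(clusters) + 1L]] <- structure(
      list(centre = c(xc[i], yc[j]), centroid = c(cx, cy),
           population = pop, min_value = v[c0],
           representative_point = members[which.min(d2)]),
      class = "fes_cluster")
  }
  clusters[order(-vapply(clusters, function(x) x$population, 0))]
}

## ---- hydrogen-bond occupancy ---------------------------------------------

#' Backbone hydrogen-bond occupancy across an ensemble
#'
#' Counts, for every donor/acceptor backbone pair at least two residues
#' apart, the fraction of frames in which the amide H to carbonyl O
#' distance is within `cutoff_A` (default 2.8 A, the conventional
#' hydrogen-acceptor distance criterion). Amide hydrogens are placed when
#' absent.
#'
#' @param e a [peptide_ensemble()].
#' @param cutoff_A H...O distance cutoff in Angstrom.
#' @return A data frame with columns `donor`, `acceptor`, `occupancy_pct`,
#'   sorted by decreasing occupancy; pairs never bonded are omitted.
#' @export
hbond_occupancy <- function(e, cutoff_A = 2.8) {
  stopifnot(inherits(e, "peptide_ensemble"))
  if (!length(e$frames)) stop("hbond_occupancy: empty ensemble")
  n <- length(e$sequence)
  cnt <- matrix(0L, n, n)
  for (f in e$frames) {
    f <- place_amide_hydrogens(f)
    H <- atom_xyz(f, "H"); O <- atom_xyz(f, "O")
    d2 <- outer(rowSums(H^2), rowSums(O^2), "+") - 2 * H %*% t(O)
    bonded <- d2 <= cutoff_A^2
    bonded[is.na(bonded)] <- FALSE
    bonded[abs(outer(seq_len(n), seq_len(n), "-")) < 2] <- FALSE
    cnt <- cnt + bonded
  }
  idx <- which(cnt > 0L, arr.ind = TRUE)
  out <- data.frame(donor = idx[, 1], acceptor = idx[, 2],
                    occupancy_pct = 100 * cnt[idx] / length(e$frames))
  out <- out[order(-out$occupancy_pct, out$donor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
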