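# Analysis of centre-of-mass pulling trajectories: replicate-averaged
# helicity-versus-distance profiles, jackknife standard errors and the
# helicity-retention classification separating conformational-selection
# from binding-induced-folding behaviour.

#' Construct a pulling replicate set
#'
#' Holds per-replicate time series of (COM distance, helical residue count)
#' for a peptide pulled away from its receptor-bound state.
#'
#' @param replicates list of data frames, each with columns `frame`,
#'   `com_distance_nm` (non-decreasing within a replicate) and
#'   `helical_count`.
#' @param peptide peptide name.
#' @param n_residues residue count of the pulled peptide.
#' @return An object of class `pull_replicate_set`.
#' @export
pull_replicate_set <- function(replicates, peptide = "peptide",
                               n_residues) {
  if (!is.list(replicates) || !length(replicates))
    stop("pull_replicate_set: empty replicate list")
  for (r in replicates) {
    if (!all(c("frame", "com_distance_nm", "helical_count") %in% names(r)))
      stop("pull_replicate_set: replicate columns must be frame, ",
           "com_distance_nm, helical_count")
    if (is.unsorted(r$com_distance_nm))
      stop("pull_replicate_set: com_distance_nm must be non-decreasing ",
           "within each replicate")
    if (any(r$helical_count < 0 | r$helical_count > n_residues))
      stop("pull_replicate_set: helical_count outside [0, n_residues]")
  }
  structure(list(replicates = unname(replicates), peptide = peptide,
                 n_residues = n_residues),
            class = "pull_replicate_set")
}

#' @export
print.pull_replicate_set <- function(x, ...) {
  cat(sprintf("<pull_replicate_set> %s: %d replicates, %d residues\n",
              x$peptide, length(x$replicates), x$n_residues))
  invisible(x)
}

#' Jackknife standard error across replicates
#'
#' Leave-one-out standard error of the mean of one value per replicate:
#' with leave-one-out means `theta_i`,
#' `SE = sqrt((n - 1)/n * sum((theta_i - mean(theta))^2))`. For n = 2 this
#' reduces to `|a - b| / 2`.
#'
#' @param values numeric vector, one value per replicate (n >= 2).
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("jackknife_se: need at least 2 replicates")
  tot <- sum(values)
  loo <- (tot - values) / (n - 1)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Replicate-averaged helicity profile
#'
#' Averages per-frame helical residue counts across replicates, either
#' pointwise on the shared time grid (the convention when replicates share
#' a pulling schedule) or within COM-distance bins, and attaches jackknife
#' standard errors computed across replicate means at each grid point.
#'
#' @param p a [pull_replicate_set()].
#' @param align_by `"time_index"` (default) or `"distance_bin"`.
#' @param bin_width_nm distance-bin width for `align_by = "distance_bin"`
#'   (default 0.05 nm).
#' @return An object of class `pull_profile`: list with `index` (time index
#'   or bin centre), `mean_com_distance_nm`, `mean_helical_count`,
#'   `jackknife_se` (NA when only one replicate contributes),
#'   `n_replicates`, `peptide`, `n_residues`, `align_by`.
#' @export
helicity_profile <- function(p, align_by = c("time_index", "distance_bin"),
                             bin_width_nm = 0.05) {
  stopifnot(inherits(p, "pull_replicate_set"))
  align_by <- match.arg(align_by)
  reps <- p$replicates
  nr <- length(reps)
  if (align_by == "time_index") {
    grids <- lapply(reps, `[[`, "frame")
    if (length(unique(vapply(grids, length, 0L))) != 1L ||
        !all(vapply(grids, function(g) all(g == grids[[1]]), TRUE)))
      stop("helicity_profile: replicates do not share a time grid")
    hmat <- vapply(reps, `[[`, numeric(length(grids[[1]])),
                   "helical_count")
    dmat <- vapply(reps, `[[`, numeric(length(grids[[1]])),
                   "com_distance_nm")
    hmat <- matrix(hmat, ncol = nr); dmat <- matrix(dmat, ncol = nr)
    se <- if (nr >= 2) apply(hmat, 1, jackknife_se) else
      rep(NA_real_, nrow(hmat))
    out <- list(index = grids[[1]],
                mean_com_distance_nm = rowMeans(dmat),
                mean_helical_count = rowMeans(hmat),
                jackknife_se = se)
  } else {
    lo <- vapply(reps, function(r) min(r$com_distance_nm), 0)
    hi <- vapply(reps, function(r) max(r$com_distance_nm), 0)
    if (max(lo) >= min(hi))
      stop("helicity_profile: replicates have disjoint distance supports")
    edges <- seq(floor(max(lo) / bin_width_nm) * bin_width_nm,
                 ceiling(min(hi) / bin_width_nm) * bin_width_nm,
                 by = bin_width_nm)
    ctr <- (edges[-1] + edges[-length(edges)]) / 2
    permean <- vapply(reps, function(r) {
      b <- findInterval(r$com_distance_nm, edges, rightmost.closed = TRUE)
      vapply(seq_along(ctr), function(k) {
        v <- r$helical_count[b == k]
        if (length(v)) mean(v) else NA_real_
      }, 0)
    }, numeric(length(ctr)))
    permean <- matrix(permean, ncol = nr)
    keep <- rowSums(!is.na(permean)) == nr   # bins covered by all replicates
    se <- if (nr >= 2) apply(permean[keep, , drop = FALSE], 1,
                             jackknife_se) else
      rep(NA_real_, sum(keep))
    out <- list(index = ctr[keep],
                mean_com_distance_nm = ctr[keep],
                mean_helical_count = rowMeans(permean[keep, , drop = FALSE]),
                jackknife_se = se)
  }
  structure(c(out, list(n_replicates = nr, peptide = p$peptide,
                        n_residues = p$n_residues, align_by = align_by)),
            class = "pull_profile")
}

#' @export
print.pull_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<pull_profile> %s: %d points, %d replicates (%s)\n",
    "  COM distance %.2f-%.2f nm, helical count %.1f -> %.1f\n"),
    x$peptide, length(x$index), x$n_replicates, x$align_by,
    min(x$mean_com_distance_nm), max(x$mean_com_distance_nm),
    x$mean_helical_count[1],
    x$mean_helical_count[length(x$mean_helical_count)]))
  invisible(x)
}

#' Classify helicity retention under pulling
#'
#' A peptide "retains helicity" when its mean helical residue count at the
#' probe distance is at least `retain_fraction` of the count at the start
#' distance; otherwise it "loses helicity". The defaults (start 1.33 nm,
#' probe 1.8 nm, 50% retention) encode the contrast between p53-P27S-like
#' conformational selection and 12/1-like binding-induced folding.
#'
#' Profile values are read at the grid points nearest in mean COM distance.
#'
#' @param profile a [helicity_profile()] result.
#' @param start_distance_nm,probe_distance_nm distances in nm.
#' @param retain_fraction retention threshold in (0, 1\].
#' @return A list with `call` ("retains_helicity" or "loses_helicity"),
#'   `count_at_start`, `count_at_probe`, `threshold` and the parameters.
#' @export
classify_retention <- function(profile, start_distance_nm = 1.33,
                               probe_distance_nm = 1.8,
                               retain_fraction = 0.5) {
  stopifnot(inherits(profile, "pull_profile"))
  d <- profile$mean_com_distance_nm
  if (probe_distance_nm > max(d) + 1e-9 ||
      probe_distance_nm < min(d) - 1e-9)
    stop("classify_retention: probe distance outside profile support")
  at <- function(x) profile$mean_helical_count[which.min(abs(d - x))]
  h0 <- at(start_distance_nm); h1 <- at(probe_distance_nm)
  call <- if (h1 >= retain_fraction * h0) "retains_helicity" else
    "loses_helicity"
  list(call = call, count_at_start = h0, count_at_probe = h1,
       threshold = retain_fraction * h0,
       start_distance_nm = start_distance_nm,
       probe_distance_nm = probe_distance_nm,
       retain_fraction = retain_fraction)
}
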