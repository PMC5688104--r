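# Synthetic conformational ensembles and pulling replicates with
# prescribed statistical structure, so every analysis stage can be tested
# without molecular-dynamics trajectories. The equilibrium generator plants
# contiguous dihedral-state blocks (alpha-helix, beta, polyproline II,
# coil) with prescribed populations and angular noise; the pulling
# generator produces replicate helicity-versus-distance decays with
# presets emulating "retains helicity" and "loses helicity" behaviour.

#' Specification of a synthetic equilibrium ensemble
#'
#' @param sequence peptide sequence (default the 12/1 peptide).
#' @param n_frames number of conformations to generate.
#' @param weights named or positional weights over the dihedral states
#'   `helix`, `beta`, `ppii`, `coil` (non-negative, normalized to sum 1).
#' @param noise_sd_deg Gaussian dihedral noise, degrees (default 10).
#' @param block_mean_len mean length of contiguous state blocks, residues
#'   (geometric length distribution; default 6). Blocks rather than
#'   independent per-residue states are required for hydrogen-bond based
#'   assignment to see helices at all.
#' @param seed integer seed.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(sequence = peptide_sequence("MPRFMDYWEGLN",
                                                      name = "12/1"),
                          n_frames = 100,
                          weights = c(helix = 0.3, beta = 0.2,
                                      ppii = 0.2, coil = 0.3),
                          noise_sd_deg = 10, block_mean_len = 6,
                          seed = 1) {
  sequence <- as_peptide_sequence(sequence)
  if (length(weights) != 4 || any(weights < 0) || sum(weights) <= 0)
    stop("ensemble_spec: weights must be 4 non-negative values, sum > 0")
  if (is.null(names(weights)))
    names(weights) <- c("helix", "beta", "ppii", "coil")
  weights <- weights / sum(weights)
  if (n_frames < 1) stop("ensemble_spec: n_frames must be >= 1")
  if (noise_sd_deg < 0) stop("ensemble_spec: noise sd must be >= 0")
  structure(list(sequence = sequence, n_frames = as.integer(n_frames),
                 weights = weights, noise_sd_deg = noise_sd_deg,
                 block_mean_len = block_mean_len, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# dihedral-state centres (phi, psi) in degrees
.state_centers <- rbind(helix = c(-57, -47), beta = c(-135, 135),
                        ppii = c(-75, 150))

#' Generate a synthetic equilibrium ensemble
#'
#' Generates conformations whose residues are segmented into contiguous
#' blocks of dihedral states sampled from the prescribed weights; each
#' residue's (phi, psi) is the state centre (helix (-57, -47), beta
#' (-135, 135), polyproline II (-75, 150), coil uniform) plus Gaussian
#' noise, and structures are built with [build_from_dihedrals()].
#'
#' Two ground-truth label sets are stored for oracle comparisons: `state`,
#' the planted per-residue dihedral state, and `h_expected`, the
#' alpha-helical (H) labels of the idealized noise-free conformation --
#' i.e. the secondary structure the planted dihedrals encode before noise
#' is added. Hydrogen-bond based assignment only recognizes helical runs
#' long enough to chain i -> i+4 bonds, so the planted helix-state
#' fraction systematically exceeds the hydrogen-bond-visible helix
#' fraction on short peptides; `h_expected` is the planted truth at the
#' level the analysis observes.
#'
#' @param spec an [ensemble_spec()].
#' @return An annotated-ready [peptide_ensemble()] with extra elements
#'   `labels` (list: character matrix `state` and logical matrix
#'   `h_expected`, frames x residues) and `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n <- length(spec$sequence)
  nf <- spec$n_frames
  p_len <- 1 / spec$block_mean_len
  states <- names(spec$weights)
  state_mat <- matrix(NA_character_, nf, n)
  h_mat <- matrix(FALSE, nf, n)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    st <- character(n)
    pos <- 1L
    while (pos <= n) {
      s <- sample(states, 1, prob = spec$weights)
      len <- min(1L + stats::rgeom(1, p_len), n - pos + 1L)
      st[pos:(pos + len - 1L)] <- s
      pos <- pos + len
    }
    phi <- psi <- numeric(n)
    for (s in rownames(.state_centers)) {
      sel <- st == s
      if (!any(sel)) next
      phi[sel] <- .state_centers[s, 1]
      psi[sel] <- .state_centers[s, 2]
    }
    sel <- st == "coil"
    phi[sel] <- stats::runif(sum(sel), -180, 180)
    psi[sel] <- stats::runif(sum(sel), -180, 180)
    ideal <- build_from_dihedrals(spec$sequence, phi, psi)
    phi_n <- wrap180(phi + stats::rnorm(n, 0, spec$noise_sd_deg))
    psi_n <- wrap180(psi + stats::rnorm(n, 0, spec$noise_sd_deg))
    frames[[f]] <- build_from_dihedrals(spec$sequence, phi_n, psi_n)
    state_mat[f, ] <- st
    h_mat[f, ] <- assign_dssp(ideal)$dssp == "H"
  }
  e <- peptide_ensemble(frames)
  e$labels <- list(state = state_mat, h_expected = h_mat)
  e$spec <- spec
  e
}

## ---- pulling generator ---------------------------------------------------

#' Specification of a synthetic pulling experiment
#'
#' Replicate trajectories in which the peptide-receptor COM distance grows
#' deterministically from `start_distance_nm` while the helical residue
#' count decays along a logistic unwinding curve with replicate-level
#' integer noise whose spread grows with distance (pulled peptides become
#' increasingly disordered).
#'
#' @param peptide peptide name.
#' @param n_residues residue count (default 12).
#' @param n_helical_start helical residues in the bound state (default 9).
#' @param n_replicates number of replicates (default 10).
#' @param n_frames frames per replicate (default 120).
#' @param start_distance_nm starting COM distance (default 1.33 nm).
#' @param pull_rate_nm_per_frame distance increment per frame (default
#'   0.01 nm, i.e. 0.1 nm/ns sampled every 0.1 ns).
#' @param midpoint_nm logistic unwinding midpoint (nm).
#' @param steepness_nm logistic width (nm).
#' @param floor retained helical fraction at large distance, in \[0, 1\].
#' @param noise_sd helical-count noise s.d. at the start distance
#'   (residues; default 0.5).
#' @param noise_growth relative growth of the noise s.d. per nm pulled
#'   (default 0.8).
#' @param seed integer seed.
#' @return A list of class `pull_spec`.
#' @export
pull_spec <- function(peptide = "peptide", n_residues = 12,
                      n_helical_start = 9, n_replicates = 10,
                      n_frames = 120, start_distance_nm = 1.33,
                      pull_rate_nm_per_frame = 0.01,
                      midpoint_nm = 1.8, steepness_nm = 0.1, floor = 0,
                      noise_sd = 0.5, noise_growth = 0.8, seed = 1) {
  if (n_replicates < 2) stop("pull_spec: need >= 2 replicates")
  if (start_distance_nm <= 0) stop("pull_spec: start distance must be > 0")
  if (floor < 0 || floor > 1) stop("pull_spec: floor must be in [0, 1]")
  if (midpoint_nm <= start_distance_nm && floor > 0)
    stop("pull_spec: degenerate preset: unwinding midpoint before the ",
         "start distance with a non-zero floor")
  structure(list(peptide = peptide, n_residues = as.integer(n_residues),
                 n_helical_start = n_helical_start,
                 n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames),
                 start_distance_nm = start_distance_nm,
                 pull_rate_nm_per_frame = pull_rate_nm_per_frame,
                 midpoint_nm = midpoint_nm, steepness_nm = steepness_nm,
                 floor = floor, noise_sd = noise_sd,
                 noise_growth = noise_growth, seed = as.integer(seed)),
            class = "pull_spec")
}

#' Preset pulling specifications
#'
#' Two presets bracketing the observed behaviours: `"p53-like"` (unwinding
#' midpoint 2.3 nm, floor 0.5 -- the peptide keeps at least half its
#' helicity at long distances, as p53-P27S does) and `"12/1-like"`
#' (midpoint 1.65 nm, floor 0 -- helicity is lost shortly after the
#' peptide leaves the binding site, as 12/1 does).
#'
#' @param preset `"p53-like"` or `"12/1-like"`.
#' @param ... overrides passed to [pull_spec()].
#' @return A [pull_spec()].
#' @export
pull_preset <- function(preset = c("p53-like", "12/1-like"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "p53-like") {
    list(peptide = "p53-P27S-like", midpoint_nm = 2.3,
         steepness_nm = 0.12, floor = 0.5, n_helical_start = 9)
  } else {
    list(peptide = "12/1-like", midpoint_nm = 1.65, steepness_nm = 0.08,
         floor = 0, n_helical_start = 8)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(pull_spec, args)
}

#' Generate synthetic pulling replicates
#'
#' COM distance increases deterministically per the pulling schedule; the
#' helical residue count follows
#' `round(n_helical_start * f(d)) + integer noise`, clamped to
#' `[0, n_residues]`, where `f(d) = floor + (1 - floor) /
#' (1 + exp((d - midpoint)/steepness))` and the noise s.d. grows with
#' distance. Each replicate draws an independent noise stream from the
#' spec seed.
#'
#' @param spec a [pull_spec()].
#' @return A [pull_replicate_set()] with the spec attached as `$spec`.
#' @export
generate_pulling_replicates <- function(spec) {
  stopifnot(inherits(spec, "pull_spec"))
  set.seed(spec$seed)
  d <- spec$start_distance_nm +
    spec$pull_rate_nm_per_frame * (seq_len(spec$n_frames) - 1L)
  frac <- spec$floor + (1 - spec$floor) /
    (1 + exp((d - spec$midpoint_nm) / spec$steepness_nm))
  sd_d <- spec$noise_sd *
    (1 + spec$noise_growth * (d - spec$start_distance_nm))
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    noise <- round(stats::rnorm(spec$n_frames, 0, sd_d))
    cnt <- round(spec$n_helical_start * frac) + noise
    cnt <- pmin(pmax(cnt, 0), spec$n_residues)
    data.frame(frame = seq_len(spec$n_frames), com_distance_nm = d,
               helical_count = cnt)
  })
  p <- pull_replicate_set(reps, peptide = spec$peptide,
                          n_residues = spec$n_residues)
  p$spec <- spec
  p
}

## ---- planted (RMSD, Rg) mixtures -----------------------------------------

#' Planted Gaussian mixture in (RMSD, Rg) space
#'
#' Draws points from a two-component (or k-component) Gaussian mixture in
#' the (RMSD, Rg) plane, recording the true component of every point --
#' the planted ground truth against which basin extraction is validated.
#'
#' @param n number of points.
#' @param weights component weights (normalized; default `c(0.7, 0.3)`).
#' @param centers matrix of component centres, one row per component,
#'   columns (RMSD, Rg) in nm.
#' @param sd_nm isotropic component standard deviation (default 0.05 nm).
#' @param seed integer seed.
#' @return A data frame with columns `rmsd_nm`, `rg_nm`, `component`.
#' @export
generate_rmsd_rg_mixture <- function(n, weights = c(0.7, 0.3),
                                     centers = rbind(c(0.15, 0.75),
                                                     c(0.55, 1.05)),
                                     sd_nm = 0.05, seed = 1) {
  if (nrow(centers) != length(weights))
    stop("generate_rmsd_rg_mixture: one centre row per weight")
  weights <- weights / sum(weights)
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  data.frame(
    rmsd_nm = pmax(stats::rnorm(n, centers[comp, 1], sd_nm), 0),
    rg_nm = pmax(stats::rnorm(n, centers[comp, 2], sd_nm), 0),
    component = comp)
}
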