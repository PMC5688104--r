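# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; nothing is read from disk.

# ideal secondary-structure dihedral centres
DIH_ALPHA <- c(-57, -47)
DIH_PPII <- c(-75, 145)
DIH_BETA <- c(-135, 135)

poly_ala <- function(n) strrep("A", n)

# smallest angular difference in degrees (wrap-aware)
ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

ideal_helix <- function(n = 20) {
  build_from_dihedrals(poly_ala(n), DIH_ALPHA[1], DIH_ALPHA[2])
}

# two antiparallel strands joined by a type II' turn; registers as E in
# hydrogen-bond based assignment
hairpin_structure <- function(strand = 6) {
  phi <- c(rep(DIH_BETA[1], strand), 60, -80, rep(DIH_BETA[1], strand))
  psi <- c(rep(DIH_BETA[2], strand), -120, 0, rep(DIH_BETA[2], strand))
  build_from_dihedrals(poly_ala(2 * strand + 2), phi, psi)
}

# apply a rigid rotation (unit quaternion from seed) plus translation
rigid_transform <- function(s, seed = 1, shift = c(5, -3, 11)) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  s$coords <- sweep(s$coords %*% t(R), 2, -shift)
  s
}

# brute-force minimum RMSD over rotations: coarse Euler-angle grid followed
# by local refinement; independent of the SVD route under test
grid_search_rmsd <- function(x, y, coarse_deg = 10) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  rotmat <- function(a, b, c) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  rms <- function(ang) {
    R <- rotmat(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((yc %*% t(R) - xc)^2)))
  }
  step <- coarse_deg * pi / 180
  best <- c(0, 0, 0); best_v <- rms(best)
  for (a in seq(0, 2 * pi - step, step))
    for (b in seq(0, pi, step))
      for (c in seq(0, 2 * pi - step, step)) {
        v <- rms(c(a, b, c))
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
  stats::optim(best, rms, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# leave-one-out jackknife SE by explicit subset enumeration
jackknife_se_bruteforce <- function(values) {
  n <- length(values)
  loo <- vapply(seq_len(n), function(i) mean(values[-i]), 0)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

# mixed panel of synthetic structures for assignment validation: ideal and
# noisy helices, coils, partial helices and hairpins
build_ss_panel <- function(n_structures = 50, n_res = 14, noise_sd = 8,
                           seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_structures), function(i) {
    k <- sample(4, 1)
    if (k == 1) {
      phi <- rep(DIH_ALPHA[1], n_res); psi <- rep(DIH_ALPHA[2], n_res)
    } else if (k == 2) {
      phi <- stats::runif(n_res, -180, 180)
      psi <- stats::runif(n_res, -180, 180)
    } else if (k == 3) {
      phi <- stats::runif(n_res, -180, 180)
      psi <- stats::runif(n_res, -180, 180)
      a <- sample(1:6, 1); b <- a + sample(5:7, 1)
      phi[a:b] <- DIH_ALPHA[1]; psi[a:b] <- DIH_ALPHA[2]
    } else {
      s <- (n_res - 2) %/% 2
      phi <- c(rep(DIH_BETA[1], s), 60, -80, rep(DIH_BETA[1], n_res - s - 2))
      psi <- c(rep(DIH_BETA[2], s), -120, 0, rep(DIH_BETA[2], n_res - s - 2))
    }
    build_from_dihedrals(poly_ala(n_res),
                         phi + stats::rnorm(n_res, 0, noise_sd),
                         psi + stats::rnorm(n_res, 0, noise_sd))
  })
}

# reference DSSP (mdtraj) on a multi-model PDB, simplified H/E/C alphabet;
# returns a character vector of per-model strings
reference_dssp_simplified <- function(pdb_path) {
  out_path <- tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import mdtraj as md\n",
    "t = md.load(%s)\n",
    "ss = md.compute_dssp(t, simplified=True)\n",
    "open(%s, 'w').write('\\n'.join(''.join(r) for r in ss) + '\\n')\n"),
    deparse(pdb_path), deparse(out_path))
  status <- system2("python", c("-c", shQuote(script)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path))
    stop("reference DSSP call failed: ", paste(status, collapse = "\n"))
  readLines(out_path)
}

simplify_ss <- function(labels) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", C = "C")
  map[labels]
}
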