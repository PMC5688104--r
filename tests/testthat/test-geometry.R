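test_that("build/measure dihedral round trip is exact over random traces", {
  set.seed(1)
  for (k in 1:100) {
    n <- sample(4:15, 1)
    phi <- runif(n, -179, 179)
    psi <- runif(n, -179, 179)
    omega <- ifelse(runif(n) < 0.9, 180, runif(n, 150, 179))
    s <- build_from_dihedrals(poly_ala(n), phi, psi, omega)
    m <- measure_dihedrals(s)
    expect_lt(max(ang_diff(m$phi[-1], phi[-1])), 1e-3)
    expect_lt(max(ang_diff(m$psi[-n], psi[-n])), 1e-3)
    expect_lt(max(ang_diff(m$omega[-n], omega[-n])), 1e-3)
    expect_true(is.na(m$phi[1]) && is.na(m$psi[n]) && is.na(m$omega[n]))
  }
})

test_that("builder validates inputs and handles the single-residue case", {
  expect_error(build_from_dihedrals(poly_ala(5), c(-60, -60), -45),
               "length")
  expect_error(build_from_dihedrals(poly_ala(5), NaN, -45), "non-finite")
  one <- build_from_dihedrals("A", NA, NA)
  expect_equal(n_residues <- length(one$sequence), 1L)
  expect_identical(unname(one$coords[one$atom == "N", ]), c(0, 0, 0))
})

test_that("built backbones have canonical bonded geometry", {
  s <- build_from_dihedrals(poly_ala(10), -57, -47)
  expect_silent(pepscape:::validate_backbone(s))
  d <- measure_dihedrals(s)
  expect_lt(max(abs(d$omega[-10] - 180)), 1e-6)
})

test_that("ideal alpha and PPII builds reproduce canonical helix geometry", {
  hp <- helix_parameters(ideal_helix(20))
  expect_equal(hp$rise_per_residue, 1.5, tolerance = 0.1 / 1.5)
  expect_equal(hp$residues_per_turn, 3.6, tolerance = 0.1 / 3.6)
  expect_identical(hp$handedness, "right")
  expect_lt(hp$twist_sd^2, 1e-3)  # constant twist along an ideal chain

  pp <- helix_parameters(
    build_from_dihedrals(poly_ala(20), DIH_PPII[1], DIH_PPII[2]))
  expect_equal(pp$rise_per_residue, 3.1, tolerance = 0.15 / 3.1)
  expect_equal(pp$residues_per_turn, 3.0, tolerance = 0.15 / 3.0)
  expect_identical(pp$handedness, "left")
})

test_that("helix_parameters rejects degenerate and non-helical traces", {
  ext <- build_from_dihedrals(poly_ala(10), 180, 180)
  expect_error(helix_parameters(ext), "not helical|collinear")
  expect_error(helix_parameters(ideal_helix(5)), "at least 6")
})

test_that("kabsch_rmsd is a symmetric rigid-motion-invariant metric", {
  a <- ideal_helix(12)
  expect_equal(kabsch_rmsd(a, a), 0)
  b <- rigid_transform(a, seed = 3)
  expect_lt(kabsch_rmsd(a, b), 1e-6)
  set.seed(9)
  c1 <- a
  c1$coords <- c1$coords + matrix(rnorm(length(c1$coords), 0, 0.8),
                                  ncol = 3)
  expect_equal(kabsch_rmsd(a, c1), kabsch_rmsd(c1, a))
  expect_gt(kabsch_rmsd(a, c1), 0)
  expect_error(kabsch_rmsd(a, ideal_helix(10)), "residue counts")
})

test_that("kabsch_rmsd matches a rotation-grid brute force on a reflected
           planar toy and bio3d on random pairs", {
  # 4-point planar configuration and its mirror image: reflections are not
  # rigid motions, so the minimum RMSD is strictly positive
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 2, 0), c(0.5, 1.5, 1.2))
  y <- x %*% diag(c(1, 1, -1))
  expect_equal(pepscape:::kabsch_rmsd_xyz(x, y), grid_search_rmsd(x, y),
               tolerance = 1e-5)
  expect_gt(pepscape:::kabsch_rmsd_xyz(x, y), 0.1)

  set.seed(4)
  for (k in 1:5) {
    p <- matrix(rnorm(30), ncol = 3)
    q <- p + matrix(rnorm(30, 0, 0.5), ncol = 3)
    # bio3d prints/rounds RMSD to 3 decimals
    expect_equal(pepscape:::kabsch_rmsd_xyz(p, q),
                 as.numeric(bio3d::rmsd(as.vector(t(p)), as.vector(t(q)),
                                        fit = TRUE)),
                 tolerance = 1e-3)
  }
})

test_that("radius of gyration has its closed forms and invariances", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  a <- 3.7  # unit-cube corners scaled by a: Rg = a * sqrt(3) / 2
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * a
  expect_equal(radius_of_gyration(cube), sqrt(3) / 2 * a)

  s <- ideal_helix(12)
  expect_equal(radius_of_gyration(rigid_transform(s, 5)),
               radius_of_gyration(s))
  scaled <- s
  scaled$coords <- s$coords * 2.5
  expect_equal(radius_of_gyration(scaled), 2.5 * radius_of_gyration(s))
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("com_distance reports nm for Angstrom inputs", {
  g <- matrix(c(0, 0, 0), 1)
  expect_equal(com_distance(g, g), 0)
  expect_equal(com_distance(g, matrix(c(13.3, 0, 0), 1)), 1.33)
  # hand-computed two-atom mass-weighted centroids
  a <- rbind(c(0, 0, 0), c(2, 0, 0))
  b <- rbind(c(10, 0, 0), c(14, 0, 0))
  expect_equal(com_distance(a, b, mass_a = c(1, 3), mass_b = c(2, 2)),
               (12 - 1.5) / 10)
  expect_error(com_distance(matrix(numeric(0), 0, 3), g), "empty")
})
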