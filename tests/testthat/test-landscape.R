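test_that("helicity metrics are zero for coil and saturated for ideal", {
  coil <- peptide_ensemble(lapply(1:5, function(i) {
    set.seed(i)
    build_from_dihedrals(poly_ala(12), runif(12, 100, 170),
                         runif(12, -170, -100))
  }))
  m <- compute_helicity_metrics(annotate_ensemble(coil))
  expect_equal(m$pct_residues_alpha, 0)
  expect_equal(m$pct_frames_ge70, 0)

  ideal <- peptide_ensemble(replicate(4, ideal_helix(12),
                                      simplify = FALSE))
  m2 <- compute_helicity_metrics(annotate_ensemble(ideal))
  expect_equal(m2$pct_frames_within_2A, 100)
  expect_gt(m2$pct_residues_alpha, 70)
  expect_error(compute_helicity_metrics(
    annotate_ensemble(ideal), ideal_ref = ideal_helix(9)), "length")
})

test_that("metric i tracks the generator's planted helix labels", {
  sp <- ensemble_spec(n_frames = 400,
                      weights = c(helix = 0.30, beta = 0.21,
                                  ppii = 0.21, coil = 0.28),
                      seed = 7)
  e <- annotate_ensemble(generate_ensemble(sp))
  m <- compute_helicity_metrics(e)
  realized <- 100 * mean(e$labels$h_expected)
  expect_lt(abs(m$pct_residues_alpha - realized), 3)
})

test_that("metrics are invariant to frame order and rigid motion", {
  sp <- ensemble_spec(n_frames = 30, seed = 5)
  e <- generate_ensemble(sp)
  ref <- build_from_dihedrals(e$sequence, -57, -47)
  m0 <- compute_helicity_metrics(annotate_ensemble(e, ref), ref)
  perm <- peptide_ensemble(e$frames[rev(seq_along(e$frames))])
  m1 <- compute_helicity_metrics(annotate_ensemble(perm, ref), ref)
  moved <- peptide_ensemble(lapply(seq_along(e$frames), function(i)
    rigid_transform(e$frames[[i]], seed = i)))
  m2 <- compute_helicity_metrics(annotate_ensemble(moved, ref), ref)
  expect_equal(m1, m0)
  expect_equal(m2, m0)
})

test_that("fes2d reproduces closed-form population gaps", {
  # two delta-peaked states with 80/20 weights: gap = ln 4
  x <- c(rep(-60, 800), rep(-135, 200))
  y <- c(rep(-45, 800), rep(135, 200))
  f <- fes2d(x, y, seq(-180, 180, 10), seq(-180, 180, 10))
  vals <- sort(f$values[!f$mask])
  expect_length(vals, 2)
  expect_equal(vals[1], 0)
  expect_equal(vals[2], log(4))
  expect_true(all(f$mask[f$counts == 0]))
})

test_that("uniform angular sampling yields a nearly flat surface", {
  set.seed(10)
  f <- fes2d(runif(1e5, -180, 180), runif(1e5, -180, 180),
             seq(-180, 180, 10), seq(-180, 180, 10))
  expect_lt(max(f$values, na.rm = TRUE), 1.0)
})

test_that("single-conformation ensembles occupy exactly their own bins", {
  e <- peptide_ensemble(list(ideal_helix(12)))
  f <- ramachandran_fes(e)
  expect_equal(sum(f$counts), 10)  # both angles defined at residues 2..11
  expect_true(all(f$values[!f$mask] == 0))
  expect_error(ramachandran_fes(e, bin_width = 7), "divide")
})

test_that("rmsd_rg_fes honours bin widths and the reference", {
  e <- peptide_ensemble(replicate(6, ideal_helix(12), simplify = FALSE))
  ref <- ideal_helix(12)
  f <- rmsd_rg_fes(e, ref, bin_width_nm = 0.05)
  expect_equal(sum(!f$mask), 1L)  # all frames identical: one occupied bin
  expect_equal(unique(round(diff(f$x_edges), 10)), 0.05)
  expect_equal(unique(round(diff(f$y_edges), 10)), 0.05)
})

test_that("basins recover a planted 70/30 mixture", {
  mix <- generate_rmsd_rg_mixture(5000, weights = c(0.7, 0.3), seed = 11)
  f <- fes2d(mix$rmsd_nm, mix$rg_nm, seq(0, 0.9, 0.1), seq(0.4, 1.4, 0.1),
             "rmsd_nm", "rg_nm")
  cl <- extract_basins(f)
  expect_length(cl, 2)
  pops <- vapply(cl, `[[`, 0, "population")
  true1 <- 100 * mean(mix$component == 1)
  expect_lt(abs(pops[1] - true1), 3)
  expect_lt(abs(pops[2] - (100 - true1)), 3)
  # representative points lie in their own component
  expect_equal(mix$component[cl[[1]]$representative_point], 1)
  expect_equal(mix$component[cl[[2]]$representative_point], 2)
  # population filter semantics
  expect_length(extract_basins(f, min_pop_pct = 50), 1)
})

test_that("a single-Gaussian landscape yields one full-population basin", {
  m1 <- generate_rmsd_rg_mixture(5000, weights = 1,
                                 centers = rbind(c(0.3, 0.8)), seed = 2)
  f <- fes2d(m1$rmsd_nm, m1$rg_nm, seq(0, 0.7, 0.1), seq(0.4, 1.2, 0.1))
  cl <- extract_basins(f)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$population, 100)
})

test_that("basin populations sum to 100 when nothing is discarded", {
  mix <- generate_rmsd_rg_mixture(2000, weights = c(0.5, 0.5), seed = 3)
  f <- fes2d(mix$rmsd_nm, mix$rg_nm, seq(0, 0.9, 0.1), seq(0.4, 1.4, 0.1))
  cl <- extract_basins(f, min_pop_pct = 0)
  expect_equal(sum(vapply(cl, `[[`, 0, "population")), 100)
  cl2 <- extract_basins(f, min_pop_pct = 1)
  expect_lte(sum(vapply(cl2, `[[`, 0, "population")), 100)
})

test_that("hydrogen-bond occupancy finds the i -> i+4 ladder of a helix", {
  e <- peptide_ensemble(replicate(3, ideal_helix(12), simplify = FALSE))
  occ <- hbond_occupancy(e)
  expect_gt(nrow(occ), 0)
  top <- occ[occ$occupancy_pct == 100, ]
  # every i -> i+4 helical bond present at full occupancy; the only other
  # contacts under a pure 2.8 A distance criterion are the tighter
  # i -> i+3 approaches of the same helical ladder
  i4 <- top[top$donor - top$acceptor == 4, ]
  expect_equal(sort(i4$acceptor), 1:8)
  expect_true(all(top$donor - top$acceptor %in% c(3, 4)))

  ext <- peptide_ensemble(list(
    build_from_dihedrals(poly_ala(12), 180, 180)))
  expect_equal(nrow(hbond_occupancy(ext)), 0)
  expect_equal(nrow(hbond_occupancy(e, cutoff_A = 0)), 0)
})
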