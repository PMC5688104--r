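test_that("amide hydrogens are placed by the carbonyl-opposition rule", {
  s <- place_amide_hydrogens(ideal_helix(10))
  H <- pepscape:::atom_xyz(s, "H")
  N <- pepscape:::atom_xyz(s, "N")
  expect_true(all(is.na(H[1, ])))
  d <- sqrt(rowSums((H - N)^2))[-1]
  expect_equal(d, rep(1.0, 9))
  # idempotence: a second pass changes nothing
  expect_identical(place_amide_hydrogens(s), s)
})

test_that("prolines receive no amide hydrogen", {
  s <- build_from_dihedrals(peptide_sequence("APAPAA"), -57, -47)
  s <- place_amide_hydrogens(s)
  n_h <- sum(s$atom == "H")
  expect_equal(n_h, 6 - 1 - 2)  # residues 2..n minus the two prolines
  expect_false(pepscape:::has_atom(s, "H", 2))
  expect_false(pepscape:::has_atom(s, "H", 4))
})

test_that("Kabsch-Sander energy declares the i -> i+4 helix bond", {
  s <- place_amide_hydrogens(ideal_helix(12))
  e <- kabsch_sander_energy(s, donor = 8, acceptor = 4)
  expect_lt(e, -0.5)
  # donor/acceptor order matters: the reversed pair is not a bond
  expect_gt(kabsch_sander_energy(s, donor = 4, acceptor = 8), -0.5)
  # rigid motion leaves the energy unchanged
  s2 <- rigid_transform(s, seed = 8)
  expect_equal(kabsch_sander_energy(s2, 8, 4), e)
  expect_error(kabsch_sander_energy(s, 5, 4), ">= 2 residues")
})

test_that("Kabsch-Sander energy nearly cancels for distant residues", {
  ext <- place_amide_hydrogens(
    build_from_dihedrals(poly_ala(30), 180, 180))
  # fully extended chain: residues 25 apart are tens of Angstrom away
  expect_lt(abs(kabsch_sander_energy(ext, 28, 3)), 0.05)
})

test_that("ideal helix is assigned a contiguous interior run of H", {
  lab <- assign_dssp(ideal_helix(20))$dssp
  runs <- rle(lab)
  expect_gte(max(runs$lengths[runs$values == "H"]), 12)
  expect_identical(lab[1], "C")
  expect_identical(lab[20], "C")
})

test_that("fully extended single chain has no helix and no strand", {
  lab <- assign_dssp(build_from_dihedrals(poly_ala(12), 180, 180))$dssp
  expect_false(any(lab %in% c("H", "G", "I", "E", "B")))
})

test_that("antiparallel hairpin registers E on both strands", {
  s <- hairpin_structure(6)
  lab <- assign_dssp(s)$dssp
  expect_gte(sum(lab[1:6] == "E"), 3)
  expect_gte(sum(lab[9:14] == "E"), 3)
})

test_that("chains shorter than 3 residues are all-coil", {
  s <- build_from_dihedrals("AA", c(NA, -60), c(-45, NA))
  expect_identical(assign_dssp(s)$dssp, c("C", "C"))
})

test_that("assignment agrees with reference DSSP on a 50-structure panel", {
  panel <- build_ss_panel(50)
  pdb <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(peptide_ensemble(panel), pdb)
  ref <- reference_dssp_simplified(pdb)
  mine <- vapply(panel, function(s)
    paste(simplify_ss(assign_dssp(s)$dssp), collapse = ""), "")
  ref_chars <- unlist(strsplit(ref, ""))
  my_chars <- unlist(strsplit(mine, ""))
  expect_length(my_chars, length(ref_chars))
  expect_gte(mean(my_chars == ref_chars), 0.95)
})

test_that("Ramachandran regions classify canonical centres and wrap", {
  expect_identical(classify_rama_region(-60, -45), "alpha")
  expect_identical(classify_rama_region(60, 45), "alphaL")
  expect_identical(classify_rama_region(-135, 135), "beta")
  expect_identical(classify_rama_region(-75, 150), "ppii")
  expect_identical(classify_rama_region(0, 0), "other")
  # wrap-aware: psi = -172 is 38 deg from the ppii centre through the seam
  expect_identical(classify_rama_region(-75, -172, half_width = 40), "ppii")
  expect_identical(classify_rama_region(-75, -172), "other")
  expect_error(classify_rama_region(NaN, 0), "non-finite")
})

test_that("region classification is total and deterministic on the torus", {
  set.seed(6)
  phi <- runif(500, -180, 180)
  psi <- runif(500, -180, 180)
  r1 <- classify_rama_region(phi, psi)
  r2 <- classify_rama_region(phi, psi)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c("alpha", "beta", "ppii", "alphaL", "other")))
})
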