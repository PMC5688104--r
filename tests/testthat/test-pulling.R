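test_that("jackknife SE has its closed forms and matches brute force", {
  expect_equal(jackknife_se(rep(4.2, 8)), 0)
  expect_equal(jackknife_se(c(3, 7)), abs(3 - 7) / 2)
  set.seed(5)
  v <- rnorm(10)
  expect_equal(jackknife_se(v), jackknife_se_bruteforce(v),
               tolerance = 1e-12)
  expect_error(jackknife_se(1), "at least 2")
})

test_that("flat replicates give a flat profile with zero error", {
  reps <- lapply(1:10, function(r)
    data.frame(frame = 1:50, com_distance_nm = seq(1.33, 2.3, length = 50),
               helical_count = 9))
  p <- pull_replicate_set(reps, "const", n_residues = 12)
  prof <- helicity_profile(p)
  expect_true(all(prof$mean_helical_count == 9))
  expect_true(all(prof$jackknife_se == 0))
  expect_identical(classify_retention(prof)$call, "retains_helicity")
})

test_that("profile is invariant to replicate order", {
  p <- generate_pulling_replicates(pull_preset("12/1-like", seed = 4))
  prof1 <- helicity_profile(p)
  p2 <- p
  p2$replicates <- rev(p2$replicates)
  prof2 <- helicity_profile(p2)
  expect_equal(prof2$mean_helical_count, prof1$mean_helical_count)
  expect_equal(prof2$jackknife_se, prof1$jackknife_se)
})

test_that("fitted logistic midpoint of the mean profile recovers 1.6 nm", {
  sp <- pull_spec(midpoint_nm = 1.6, steepness_nm = 0.1, floor = 0,
                  noise_sd = 0.5, noise_growth = 0, n_helical_start = 9,
                  seed = 3)
  prof <- helicity_profile(generate_pulling_replicates(sp))
  d <- prof$mean_com_distance_nm
  h <- prof$mean_helical_count
  fit <- nls(h ~ a / (1 + exp((d - m) / s)),
             start = list(a = 9, m = 1.5, s = 0.12))
  expect_lt(abs(coef(fit)[["m"]] - 1.6), 0.05)
})

test_that("a single replicate averages to itself with undefined error", {
  rep1 <- data.frame(frame = 1:20,
                     com_distance_nm = seq(1.33, 1.9, length = 20),
                     helical_count = rep(c(9, 8), 10))
  p <- pull_replicate_set(list(rep1), "solo", n_residues = 12)
  prof <- helicity_profile(p)
  expect_equal(prof$mean_helical_count, rep1$helical_count)
  expect_true(all(is.na(prof$jackknife_se)))
})

test_that("distance-bin alignment handles shifted schedules", {
  reps <- lapply(1:4, function(r)
    data.frame(frame = 1:60,
               com_distance_nm = seq(1.3 + 0.01 * r, 2.2 + 0.01 * r,
                                     length = 60),
               helical_count = 8))
  p <- pull_replicate_set(reps, "shifted", n_residues = 12)
  prof <- helicity_profile(p, align_by = "distance_bin")
  expect_true(all(prof$mean_helical_count == 8))
  disjoint <- pull_replicate_set(list(
    data.frame(frame = 1:5, com_distance_nm = seq(1.3, 1.4, length = 5),
               helical_count = 8),
    data.frame(frame = 1:5, com_distance_nm = seq(2.0, 2.1, length = 5),
               helical_count = 8)), "disjoint", n_residues = 12)
  expect_error(helicity_profile(disjoint, align_by = "distance_bin"),
               "disjoint")
})

test_that("jackknife error grows with distance when noise grows", {
  p <- generate_pulling_replicates(
    pull_spec(midpoint_nm = 2.0, noise_sd = 0.4, noise_growth = 1.5,
              seed = 6))
  prof <- helicity_profile(p)
  third <- length(prof$index) %/% 3
  early <- mean(prof$jackknife_se[1:third])
  late <- mean(prof$jackknife_se[(2 * third):length(prof$index)])
  expect_gt(late, early)
})

test_that("retention classification separates the two presets", {
  p53 <- helicity_profile(generate_pulling_replicates(
    pull_preset("p53-like", seed = 3)))
  expect_identical(classify_retention(p53)$call, "retains_helicity")
  p121 <- helicity_profile(generate_pulling_replicates(
    pull_preset("12/1-like", seed = 3)))
  expect_identical(classify_retention(p121)$call, "loses_helicity")
  expect_error(classify_retention(p53, probe_distance_nm = 5),
               "outside")
})

test_that("replicate-set invariants are enforced", {
  bad <- list(data.frame(frame = 1:3, com_distance_nm = c(1.5, 1.4, 1.6),
                         helical_count = c(5, 5, 5)))
  expect_error(pull_replicate_set(bad, n_residues = 12),
               "non-decreasing")
  expect_error(pull_spec(n_replicates = 1), ">= 2")
  expect_error(pull_spec(midpoint_nm = 1.2, floor = 0.5), "degenerate")
})
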