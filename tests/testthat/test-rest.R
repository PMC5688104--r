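test_that("lambda ladder is equally spaced from zero", {
  l <- make_lambda_ladder(8, 0.5)
  expect_length(l, 8)
  expect_equal(l[1], 0)            # the unperturbed Hamiltonian
  expect_equal(l[8], 0.5)
  expect_equal(unique(round(diff(l), 12)), 0.5 / 7)
  expect_equal(as.numeric(make_lambda_ladder(2, 0.5)), c(0, 0.5))
  expect_error(make_lambda_ladder(1), "at least 2")
  expect_error(make_lambda_ladder(8, 1), "lambda_max")
})

test_that("scaled energy has the solute-tempering functional form", {
  expect_equal(scaled_energy(-10, -4, -2, 0), -16)  # plain sum at lambda 0
  expect_equal(scaled_energy(-10, -4, -2, 0.5),
               -2 + 0.5 * (-10) + sqrt(0.5) * (-4))
  # solvent-solvent term is never scaled
  for (l in c(0, 0.2, 0.5, 0.9))
    expect_equal(scaled_energy(0, 0, -7.5, l), -7.5)
  expect_error(scaled_energy(1, 1, 1, 1), "lambda")
})

test_that("exchange probability follows the Metropolis criterion", {
  a <- list(lambda = 0, e_ss = -3, e_sw = -1, e_ww = 0)
  b <- list(lambda = 0.5, e_ss = -3, e_sw = -1, e_ww = 0)
  expect_equal(exchange_probability(a, b), 1)  # identical configurations
  a2 <- list(lambda = 0, e_ss = -5, e_sw = 0, e_ww = 0)
  b2 <- list(lambda = 0.5, e_ss = -1, e_sw = 0, e_ww = 0)
  # Delta = [Ea(xb) + Eb(xa)] - [Ea(xa) + Eb(xb)] = (-1 - 2.5) - (-5 - 0.5)
  expect_equal(exchange_probability(a2, b2), min(1, exp(-2)))
  expect_equal(exchange_probability(b2, a2),
               exchange_probability(a2, b2))
  expect_error(exchange_probability(a, a), "distinct lambda")
})

test_that("exchange move preserves the product Boltzmann distribution
           exactly on an enumerable 2-replica, 2-state system", {
  beta <- 1
  lam <- c(0, 0.5)
  # two configurations with distinct energy decompositions
  confs <- list(list(e_ss = 0, e_sw = 0, e_ww = 0.3),
                list(e_ss = 1.2, e_sw = 0.7, e_ww = 0.3))
  E <- outer(seq_along(lam), seq_along(confs), Vectorize(function(r, k)
    scaled_energy(confs[[k]]$e_ss, confs[[k]]$e_sw, confs[[k]]$e_ww,
                  lam[r])))
  # within-replica Metropolis kernel for replica r over the 2 states
  M <- lapply(1:2, function(r) {
    m <- matrix(0, 2, 2)
    m[1, 2] <- 0.5 * min(1, exp(-beta * (E[r, 2] - E[r, 1])))
    m[2, 1] <- 0.5 * min(1, exp(-beta * (E[r, 1] - E[r, 2])))
    diag(m) <- 1 - rowSums(m)
    m
  })
  # joint states (i, j): replica 1 holds i, replica 2 holds j
  joint <- expand.grid(i = 1:2, j = 1:2)
  move <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    move[a, b] <- M[[1]][joint$i[a], joint$i[b]] *
                  M[[2]][joint$j[a], joint$j[b]]
  swap <- matrix(0, 4, 4)
  for (a in 1:4) {
    i <- joint$i[a]; j <- joint$j[a]
    b <- which(joint$i == j & joint$j == i)
    p <- if (i == j) 1 else exchange_probability(
      c(list(lambda = lam[1]), confs[[i]]),
      c(list(lambda = lam[2]), confs[[j]]), beta)
    swap[a, b] <- swap[a, b] + p
    swap[a, a] <- swap[a, a] + 1 - p
  }
  P <- move %*% swap
  pi_target <- exp(-beta * (E[1, joint$i] + E[2, joint$j]))
  pi_target <- pi_target / sum(pi_target)
  # stationary distribution from the unit left eigenvector
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  pi_hat <- Re(ev$vectors[, k]); pi_hat <- pi_hat / sum(pi_hat)
  expect_equal(pi_hat, pi_target, tolerance = 1e-12)
  # and the chain is a proper stochastic matrix
  expect_equal(rowSums(P), rep(1, 4))
})

test_that("identical seeds give bit-identical runs", {
  pot <- double_well_potential()
  r1 <- run_toy_rest(pot, n_sweeps = 1500, seed = 5)
  r2 <- run_toy_rest(pot, n_sweeps = 1500, seed = 5)
  expect_identical(r1$exchange_log, r2$exchange_log)
  expect_identical(r1$samples, r2$samples)
})

test_that("all exchanges are accepted when the solute terms vanish", {
  # E_ss = E_sw = 0: all replicas share the Hamiltonian, Delta = 0
  flat <- double_well_potential(barrier = 0, tilt = 0, e_ww = 1)
  r <- run_toy_rest(flat, make_lambda_ladder(2, 0.5), n_sweeps = 500,
                    seed = 2)
  expect_true(all(r$exchange_log$accepted))
  expect_equal(r$acceptance, 1)
})

test_that("exchange acceptance does not increase with ladder spacing", {
  pot <- double_well_potential(barrier = 6, tilt = 3)
  acc <- vapply(c(0.125, 0.25, 0.5), function(lmax) {
    r <- run_toy_rest(pot, make_lambda_ladder(8, lmax), n_sweeps = 4000,
                      seed = 9)
    mean(r$exchange_log$accepted)
  }, 0)
  expect_true(all(diff(acc) <= 0))
})

test_that("the lambda = 0 marginal matches direct Metropolis sampling", {
  pot <- double_well_potential(barrier = 4, tilt = 1)
  r <- run_toy_rest(pot, make_lambda_ladder(8, 0.5), n_sweeps = 4e4,
                    exchange_interval = 10, seed = 13, n_burn = 2000,
                    thin = 25)
  direct <- sample_direct_metropolis(pot, 0, n_sweeps = 4e4, seed = 14,
                                     n_burn = 2000, thin = 25)
  ks <- suppressWarnings(ks.test(r$samples[, 1], direct))
  n1 <- nrow(r$samples); n2 <- length(direct)
  crit_1pct <- 1.628 * sqrt((n1 + n2) / (n1 * n2))
  expect_lt(unname(ks$statistic), crit_1pct)
})
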