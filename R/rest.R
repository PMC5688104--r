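# Hamiltonian replica exchange with solute tempering, at desk scale:
# the lambda ladder, the scaled Hamiltonian, the Metropolis exchange
# criterion, and a toy sampler on a periodic double-well potential that
# exhibits lambda-accelerated barrier crossing.

#' Equally spaced lambda ladder
#'
#' Builds the ladder of solute-tempering coupling values
#' `lambda_i = lambda_max * i / (n - 1)`, i = 0..n-1. The replica at
#' lambda = 0 carries the real (unperturbed) Hamiltonian; higher rungs
#' progressively weaken solute interactions to accelerate conformational
#' sampling. The conventional production ladder uses eight replicas between
#' 0 and 0.5.
#'
#' @param n number of replicas (>= 2, default 8).
#' @param lambda_max top of the ladder, in (0, 1) (default 0.5).
#' @return Numeric vector of class `lambda_ladder`.
#' @export
make_lambda_ladder <- function(n = 8, lambda_max = 0.5) {
  if (n < 2) stop("make_lambda_ladder: need at least 2 replicas")
  if (lambda_max <= 0 || lambda_max >= 1)
    stop("make_lambda_ladder: lambda_max must be in (0, 1)")
  structure(lambda_max * (seq_len(n) - 1) / (n - 1),
            class = "lambda_ladder")
}

#' Solute-tempering scaled energy
#'
#' Total energy of a configuration under the solute-tempering Hamiltonian:
#' solute-solute interactions are scaled by `(1 - lambda)`, solute-solvent
#' by `sqrt(1 - lambda)`, and solvent-solvent left untouched:
#' `E(lambda) = (1 - lambda) E_ss + sqrt(1 - lambda) E_sw + E_ww`.
#' At lambda = 0 this is the plain sum (the unperturbed Hamiltonian).
#'
#' @param e_ss,e_sw,e_ww solute-solute, solute-solvent and solvent-solvent
#'   energy components (any consistent unit).
#' @param lambda coupling value in \[0, 1).
#' @return The scaled total energy.
#' @export
scaled_energy <- function(e_ss, e_sw, e_ww, lambda) {
  if (any(lambda < 0 | lambda >= 1))
    stop("scaled_energy: lambda must be in [0, 1)")
  (1 - lambda) * e_ss + sqrt(1 - lambda) * e_sw + e_ww
}

#' Metropolis exchange probability for adjacent replicas
#'
#' Probability of swapping the configurations of two replicas under the
#' Metropolis criterion: `p = min(1, exp(-beta * Delta))` with
#' `Delta = [E_a(x_b) + E_b(x_a)] - [E_a(x_a) + E_b(x_b)]`, where `E_r(x)`
#' is the scaled energy of configuration `x` under replica `r`'s lambda.
#' Symmetric under swapping the two replicas.
#'
#' @param a,b replica states: lists with `lambda` and the energy
#'   decomposition of the current configuration `e_ss`, `e_sw`, `e_ww`.
#' @param beta inverse temperature (1/energy unit).
#' @return The exchange probability in \[0, 1\].
#' @export
exchange_probability <- function(a, b, beta = 1) {
  if (isTRUE(all.equal(a$lambda, b$lambda)))
    stop("exchange_probability: replicas must have distinct lambda")
  ea_xa <- scaled_energy(a$e_ss, a$e_sw, a$e_ww, a$lambda)
  eb_xb <- scaled_energy(b$e_ss, b$e_sw, b$e_ww, b$lambda)
  ea_xb <- scaled_energy(b$e_ss, b$e_sw, b$e_ww, a$lambda)
  eb_xa <- scaled_energy(a$e_ss, a$e_sw, a$e_ww, b$lambda)
  if (!all(is.finite(c(ea_xa, eb_xb, ea_xb, eb_xa))))
    stop("exchange_probability: non-finite energies")
  min(1, exp(-beta * ((ea_xb + eb_xa) - (ea_xa + eb_xb))))
}

#' Periodic double-well toy potential
#'
#' One-dimensional periodic potential on a dihedral-like coordinate x in
#' (-180, 180\] degrees, decomposed the way the solute-tempering
#' Hamiltonian expects: a solute-solute term
#' `E_ss = barrier/2 * (1 - cos(2x))` with minima at 0 and 180 separated
#' by `barrier`, a solute-solvent term `E_sw = tilt/2 * (1 - cos(x))`
#' biasing the 0-degree well, and a constant solvent term `E_ww`.
#'
#' @param barrier barrier height in kT units (default 4).
#' @param tilt well asymmetry in kT units (default 1).
#' @param e_ww constant solvent-solvent energy (default 0).
#' @return A function of class `toy_potential`: `f(x)` returning a list
#'   with `e_ss`, `e_sw`, `e_ww`.
#' @export
double_well_potential <- function(barrier = 4, tilt = 1, e_ww = 0) {
  f <- function(x) {
    xr <- x * pi / 180
    list(e_ss = barrier / 2 * (1 - cos(2 * xr)),
         e_sw = tilt / 2 * (1 - cos(xr)),
         e_ww = e_ww)
  }
  class(f) <- c("toy_potential", "function")
  f
}

.toy_total <- function(pot, x, lambda) {
  e <- pot(x)
  scaled_energy(e$e_ss, e$e_sw, e$e_ww, lambda)
}

#' Run the toy replica-exchange sampler
#'
#' Alternates Metropolis moves within each replica (Gaussian proposals on
#' the periodic coordinate) with adjacent-pair exchange attempts every
#' `exchange_interval` sweeps, using [exchange_probability()]. Even and odd
#' adjacent pairs are attempted alternately. The lambda = 0 replica samples
#' the unperturbed Boltzmann distribution; higher rungs see scaled-down
#' barriers and cross between wells more often.
#'
#' @param potential a [double_well_potential()] (or compatible function).
#' @param ladder a [make_lambda_ladder()].
#' @param n_sweeps number of Monte Carlo sweeps.
#' @param exchange_interval sweeps between exchange attempts (default 10).
#' @param beta inverse temperature (default 1).
#' @param step_deg proposal standard deviation in degrees (default 60).
#' @param seed integer seed (required: runs are reproducible by contract).
#' @param n_burn sweeps discarded before recording (default 0).
#' @param thin record every `thin`-th sweep (default 1).
#' @return A list of class `rest_run`: `samples` (matrix, recorded sweeps x
#'   replicas, coordinates at each lambda rung), `ladder`,
#'   `exchange_log` (data frame: sweep, pair, delta, accepted),
#'   `acceptance` (per-pair exchange acceptance ratios), `move_acceptance`
#'   (per-replica within-replica acceptance).
#' @export
run_toy_rest <- function(potential, ladder = make_lambda_ladder(),
                         n_sweeps = 1e4, exchange_interval = 10,
                         beta = 1, step_deg = 60, seed,
                         n_burn = 0, thin = 1) {
  if (missing(seed)) stop("run_toy_rest: seed is required")
  set.seed(seed)
  k <- length(ladder)
  x <- rep(0, k)
  e_now <- vapply(seq_len(k), function(r)
    .toy_total(potential, x[r], ladder[r]), 0)
  nrec <- floor((n_sweeps - n_burn) / thin)
  samples <- matrix(NA_real_, nrec, k)
  rec <- 0L
  moves_acc <- moves_tot <- rep(0, k)
  log_sweep <- integer(0); log_pair <- integer(0)
  log_delta <- numeric(0); log_acc <- logical(0)
  parity <- 0L
  for (sw in seq_len(n_sweeps)) {
    prop <- wrap180(x + stats::rnorm(k, 0, step_deg))
    e_prop <- vapply(seq_len(k), function(r)
      .toy_total(potential, prop[r], ladder[r]), 0)
    acc <- log(stats::runif(k)) < -beta * (e_prop - e_now)
    x[acc] <- prop[acc]; e_now[acc] <- e_prop[acc]
    moves_acc <- moves_acc + acc; moves_tot <- moves_tot + 1
    if (sw %% exchange_interval == 0L) {
      first <- 1L + parity
      pairs <- if (first <= k - 1L) seq(first, k - 1L, by = 2L) else
        integer(0)
      parity <- 1L - parity
      for (p in pairs) {
        ea <- potential(x[p]); eb <- potential(x[p + 1])
        delta <- (scaled_energy(eb$e_ss, eb$e_sw, eb$e_ww, ladder[p]) +
                  scaled_energy(ea$e_ss, ea$e_sw, ea$e_ww, ladder[p + 1])) -
                 (e_now[p] + e_now[p + 1])
        accepted <- log(stats::runif(1)) < -beta * delta
        if (accepted) {
          tmp <- x[p]; x[p] <- x[p + 1]; x[p + 1] <- tmp
          e_now[p] <- scaled_energy(eb$e_ss, eb$e_sw, eb$e_ww, ladder[p])
          e_now[p + 1] <- scaled_energy(ea$e_ss, ea$e_sw, ea$e_ww,
                                        ladder[p + 1])
        }
        log_sweep <- c(log_sweep, sw); log_pair <- c(log_pair, p)
        log_delta <- c(log_delta, delta); log_acc <- c(log_acc, accepted)
      }
    }
    if (sw > n_burn && (sw - n_burn) %% thin == 0L) {
      rec <- rec + 1L
      samples[rec, ] <- x
    }
  }
  if (all(moves_acc == 0))
    warning("run_toy_rest: a replica accepted no moves; ",
            "parameterization may be non-ergodic")
  exch <- data.frame(sweep = log_sweep, pair = log_pair,
                     delta = log_delta, accepted = log_acc)
  acc_ratio <- vapply(seq_len(length(ladder) - 1L), function(p) {
    sel <- exch$pair == p
    if (!any(sel)) NA_real_ else mean(exch$accepted[sel])
  }, 0)
  structure(list(samples = samples[seq_len(rec), , drop = FALSE],
                 ladder = ladder, exchange_log = exch,
                 acceptance = acc_ratio,
                 move_acceptance = moves_acc / moves_tot),
            class = "rest_run")
}

#' @export
print.rest_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<rest_run> %d replicas (lambda 0..%.3g), %d recorded sweeps\n",
    "  exchange acceptance per pair: %s\n"),
    length(x$ladder), max(x$ladder), nrow(x$samples),
    paste(sprintf("%.2f", x$acceptance), collapse = " ")))
  invisible(x)
}

#' Direct Metropolis sampling of a toy potential at fixed lambda
#'
#' Single-chain Metropolis sampler used as the independent reference for
#' the replica-exchange marginal at a given rung.
#'
#' @inheritParams run_toy_rest
#' @param lambda coupling value of the sampled rung (default 0).
#' @return Numeric vector of sampled coordinates (degrees).
#' @export
sample_direct_metropolis <- function(potential, lambda = 0,
                                     n_sweeps = 1e4, beta = 1,
                                     step_deg = 60, seed,
                                     n_burn = 0, thin = 1) {
  if (missing(seed)) stop("sample_direct_metropolis: seed is required")
  set.seed(seed)
  x <- 0
  e_now <- .toy_total(potential, x, lambda)
  out <- numeric(floor((n_sweeps - n_burn) / thin))
  rec <- 0L
  for (sw in seq_len(n_sweeps)) {
    prop <- wrap180(x + stats::rnorm(1, 0, step_deg))
    e_prop <- .toy_total(potential, prop, lambda)
    if (log(stats::runif(1)) < -beta * (e_prop - e_now)) {
      x <- prop; e_now <- e_prop
    }
    if (sw > n_burn && (sw - n_burn) %% thin == 0L) {
      rec <- rec + 1L
      out[rec] <- x
    }
  }
  out[seq_len(rec)]
}
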