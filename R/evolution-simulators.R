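#' Expected number of resistant mutants arising during expansions
#'
#' In a population grown from `n0` to `nmax` cells, every division can create
#' a resistant cell with probability `mu`, so each expansion performs
#' `nmax - n0` divisions and the expected number of resistant mutants after
#' `replatings` rounds is `mu * (nmax - n0) * replatings`.
#'
#' @param mu Probability that a division produces a resistance mutation.
#' @param n0 Seeded population size (cells).
#' @param nmax Population size at which the culture is re-plated (cells).
#' @param replatings Number of expansion rounds.
#' @return Expected number of resistant mutants (numeric scalar).
#' @examples
#' expected_mutants(2e-8, 2e6, 4e7, 1)   # 0.76
#' expected_mutants(2e-8, 2e6, 4e7, 10)  # 7.6
#' @export
expected_mutants <- function(mu, n0, nmax, replatings = 1) {
  stopifnot(is.numeric(mu), is.numeric(n0), is.numeric(nmax))
  if (mu < 0 || mu > 1) stop("'mu' must be a probability in [0, 1]")
  if (n0 < 0 || nmax < 0 || replatings < 0) stop("inputs must be non-negative")
  if (n0 > nmax) stop("'n0' must not exceed 'nmax'")
  mu * (nmax - n0) * replatings
}

#' Number of distinct resistance-conferring mutations implied by a rate ratio
#'
#' A resistance phenotype reachable through any one of `k` single-base
#' mutations arises at rate `k` times the per-base-pair mutation rate. Given
#' the phenotype-level rate and the per-bp rate, the implied number of
#' distinct resistance-inducing mutations is their ratio.
#'
#' @param mu_resistance Phenotype-level resistance mutation probability per
#'   division (default `2e-8`).
#' @param mu_bp Per base pair mutation rate per division (default `1e-9`).
#' @return Implied count of distinct resistance-inducing point mutations.
#' @export
resistance_mutation_targets <- function(mu_resistance = 2e-8, mu_bp = 1e-9) {
  if (mu_resistance <= 0 || mu_bp <= 0) stop("rates must be positive")
  mu_resistance / mu_bp
}

#' Simulation design for experimental-evolution models
#'
#' Bundles the parameters of the two stochastic simulators: the re-plating
#' waiting-time model (`mu`, `n0`, `nmax`, `cycle_days`, `n_sims`) and the
#' POT outgrowth plus replicate split model (`b`, `d`, `t_grow`,
#' `n_lineages`, `n_replicates`, `n_outgrowths`, `n_splits`).
#'
#' Birth and death rates are per cell per hour; defaults `b = 0.032`,
#' `d = 0.002` are the published HCC827 values at 20% oxygen / 2 g/L glucose.
#' The default outgrowth time `t_grow = 173` hours gives surviving lineages
#' a mean size of about 190 cells (see the methods vignette for how this
#' duration is calibrated against the analytic occupancy distribution).
#'
#' @param mu Resistance mutation probability per division.
#' @param n0 Seeded population size.
#' @param nmax Population size at re-plating.
#' @param replate_fraction Fraction of cells kept at re-plating.
#' @param b,d Birth and death rates per cell per hour.
#' @param t_grow POT outgrowth duration in hours.
#' @param n_lineages Number of uniquely barcoded founder cells.
#' @param n_replicates Number of equal parts in the replicate split.
#' @param n_outgrowths Independent POT outgrowth realisations.
#' @param n_splits Random splits per outgrowth (occupancy is averaged over
#'   all `n_outgrowths * n_splits` splits).
#' @param n_sims Number of independent waiting-time simulations.
#' @param cycle_days Duration of one grow-and-replate cycle, days.
#' @param max_cycles Cap on cycles (guards `mu = 0`); runs that never mutate
#'   are returned as censored.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(mu = 2e-8, n0 = 2e6, nmax = 4e7,
                       replate_fraction = 1 / 20,
                       b = 0.032, d = 0.002, t_grow = 173,
                       n_lineages = 10000, n_replicates = 8,
                       n_outgrowths = 1, n_splits = 10,
                       n_sims = 10000, cycle_days = 14, max_cycles = 1000) {
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (!(n0 > 0 && nmax > n0)) stop("need 0 < n0 < nmax")
  if (b < 0 || d < 0) stop("rates must be non-negative")
  if (d >= b && b > 0) warning("d >= b: growth is not supercritical")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  structure(list(mu = mu, n0 = n0, nmax = nmax,
                 replate_fraction = replate_fraction,
                 b = b, d = d, t_grow = t_grow,
                 n_lineages = as.integer(n_lineages),
                 n_replicates = as.integer(n_replicates),
                 n_outgrowths = as.integer(n_outgrowths),
                 n_splits = as.integer(n_splits),
                 n_sims = as.integer(n_sims),
                 cycle_days = cycle_days,
                 max_cycles = as.integer(max_cycles)),
            class = "sim_design")
}

#' Waiting time to the first resistance mutation under serial re-plating
#'
#' Each cycle grows the culture from `n0` to `nmax` cells (performing
#' `nmax - n0` divisions, each mutating with probability `mu`) and re-plates
#' back to `n0`; cycles repeat until the first resistance mutation occurs.
#' The cycle of first occurrence is geometric with per-cycle success
#' probability `1 - (1 - mu)^(nmax - n0)`; within the mutating cycle the
#' index of the first mutant division is drawn from its conditional
#' (truncated-geometric) law and mapped to a day through the exponential
#' growth curve of the cycle. This per-cycle construction is exact in
#' distribution for the first-occurrence time while avoiding cell-by-cell
#' bookkeeping.
#'
#' @param design A [sim_design()].
#' @param seed Optional integer seed.
#' @return A data frame with one row per simulation: `sim`, `cycle` (cycle
#'   index of the first resistant mutation), `day` (time of occurrence in
#'   days) and `censored` (`TRUE` when no mutation arose within
#'   `max_cycles`; `cycle` and `day` are then `NA`).
#' @export
simulate_replating_waiting_times <- function(design = sim_design(),
                                             seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  divisions <- design$nmax - design$n0
  # P(at least one mutation in a cycle), computed stably for tiny mu
  p_cycle <- -expm1(divisions * log1p(-design$mu))
  n <- design$n_sims
  if (p_cycle == 0) {
    return(data.frame(sim = seq_len(n), cycle = NA_integer_,
                      day = NA_real_, censored = TRUE))
  }
  cycle <- rgeom(n, p_cycle) + 1L
  censored <- cycle > design$max_cycles
  # conditional index of the first mutant division within the mutating cycle:
  # F(m) = (1 - (1-mu)^m) / p_cycle, inverted at a uniform draw
  u <- runif(n)
  m <- ceiling(log1p(-u * p_cycle) / log1p(-design$mu))
  m <- pmin(pmax(m, 1), divisions)
  # map division index to time through exponential growth n0 -> nmax
  frac <- log((design$n0 + m) / design$n0) / log(design$nmax / design$n0)
  day <- (cycle - 1) * design$cycle_days + frac * design$cycle_days
  cycle[censored] <- NA_integer_
  day[censored] <- NA_real_
  data.frame(sim = seq_len(n), cycle = cycle, day = day, censored = censored)
}

#' Exact stochastic (Gillespie) simulation of linear birth-death growth
#'
#' Simulates a population in which each of `n` cells divides at rate `b` and
#' dies at rate `d` (per cell per hour), using exponential waiting times
#' between events. With `trajectory = TRUE` a single lineage's full event
#' history is returned; otherwise only final sizes at `t_end` for
#' `n_lineages` independent lineages.
#'
#' @param b,d Birth and death rates per cell per hour.
#' @param t_end End time (hours).
#' @param start_size Initial population size per lineage.
#' @param n_lineages Number of independent lineages (ignored when
#'   `trajectory = TRUE`).
#' @param size_cap Optional size at which a trajectory stops early.
#' @param trajectory Return the full event trajectory of one lineage?
#' @param seed Optional integer seed.
#' @return Integer vector of final sizes, or (for `trajectory = TRUE`) a
#'   data frame with columns `time` and `size`.
#' @export
gillespie_birth_death <- function(b, d, t_end, start_size = 1,
                                  n_lineages = 1, size_cap = NULL,
                                  trajectory = FALSE, seed = NULL) {
  if (b < 0 || d < 0) stop("rates must be non-negative")
  if (start_size < 1) stop("'start_size' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (trajectory) {
    tr <- bd_trajectory_cpp(b, d, t_end,
                            if (is.null(size_cap)) 0L else as.integer(size_cap),
                            as.integer(start_size))
    return(data.frame(time = tr$time, size = tr$size))
  }
  bd_final_sizes_cpp(as.integer(n_lineages), b, d, t_end,
                     as.integer(start_size))
}

#' Exact replicate-occupancy distribution for a clone of n cells
#'
#' When `n` cells are placed uniformly at random into `R` equal replicates,
#' the probability that exactly `k` replicates receive at least one cell is
#' obtained by inclusion-exclusion over the multinomial placement:
#' \deqn{P(k) = \binom{R}{k} \sum_{j=0}^{k} (-1)^j \binom{k}{j}
#'       \left(\frac{k-j}{R}\right)^n.}
#' This is the analytic oracle against which the Monte Carlo split simulator
#' is checked.
#'
#' @param n Number of cells in the clone (scalar, >= 0).
#' @param R Number of replicates.
#' @return Named numeric vector of probabilities for k = 0, ..., R.
#' @export
occupancy_distribution_exact <- function(n, R = 8) {
  stopifnot(length(n) == 1, n >= 0, R >= 1)
  p <- vapply(0:R, function(k) {
    if (k == 0) return(as.numeric(n == 0))
    j <- 0:k
    choose(R, k) * sum((-1)^j * choose(k, j) * ((k - j) / R)^n)
  }, numeric(1))
  p[p < 0] <- 0  # guard tiny negative round-off in the alternating sum
  names(p) <- as.character(0:R)
  p
}

#' Mixture of exact occupancy distributions over observed clone sizes
#'
#' @param sizes Integer vector of clone sizes (zeros, i.e. extinct clones,
#'   are dropped).
#' @param R Number of replicates.
#' @return Named numeric vector of probabilities for k = 0, ..., R.
#' @export
occupancy_mixture_exact <- function(sizes, R = 8) {
  sizes <- sizes[sizes > 0]
  if (!length(sizes)) stop("no surviving clones")
  tab <- table(sizes)
  ns <- as.integer(names(tab))
  w <- as.numeric(tab) / sum(tab)
  out <- numeric(R + 1)
  for (i in seq_along(ns)) {
    out <- out + w[i] * occupancy_distribution_exact(ns[i], R)
  }
  names(out) <- as.character(0:R)
  out
}

#' Simulate POT outgrowth and random equal replicate split
#'
#' Grows each of `n_lineages` uniquely barcoded founder cells by exact
#' Gillespie birth-death for `t_grow` hours, discards extinct lineages,
#' pools the surviving cells, and splits the pool into `n_replicates` equal
#' parts uniformly at random without replacement (a random permutation of
#' the physical cells, i.e. a multivariate hypergeometric split). The
#' fraction of surviving barcodes present in exactly k replicates is
#' averaged over `n_outgrowths * n_splits` splits.
#'
#' @param design A [sim_design()].
#' @param seed Optional integer seed.
#' @return A list of class `occupancy_result` with elements `occupancy`
#'   (mean fraction of surviving barcodes in exactly k replicates, k =
#'   0..R), `per_split` (splits-by-(R+1) matrix of per-split fractions),
#'   `exact` (analytic mixture over the realised clone sizes), `se`
#'   (Monte Carlo standard error of each occupancy estimate),
#'   `n_surviving`, `mean_clone_size`, and `sizes` (surviving clone sizes
#'   of the last outgrowth).
#' @export
simulate_pot_split <- function(design = sim_design(), seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  R <- design$n_replicates
  per_split <- NULL
  exact_acc <- numeric(R + 1)
  n_surv_tot <- 0L
  size_sum <- 0
  sizes_last <- NULL
  for (g in seq_len(design$n_outgrowths)) {
    sizes <- bd_final_sizes_cpp(design$n_lineages, design$b, design$d,
                                design$t_grow, 1L)
    surv <- sizes[sizes > 0L]
    if (!length(surv)) stop("all lineages went extinct during outgrowth")
    sizes_last <- surv
    n_surv <- length(surv)
    n_surv_tot <- n_surv_tot + n_surv
    size_sum <- size_sum + sum(surv)
    exact_acc <- exact_acc + n_surv * occupancy_mixture_exact(surv, R)
    N <- sum(surv)
    barcode_of_cell <- rep.int(seq_len(n_surv), surv)
    part_sizes <- diff(round(seq(0, N, length.out = R + 1)))
    labels0 <- rep.int(seq_len(R), part_sizes)
    for (s in seq_len(design$n_splits)) {
      lab <- labels0[sample.int(N)]
      key <- (barcode_of_cell - 1L) * R + lab
      present <- tabulate(key, nbins = n_surv * R) > 0L
      k <- rowSums(matrix(present, ncol = R, byrow = TRUE))
      frac <- tabulate(k + 1L, nbins = R + 1L) / n_surv
      per_split <- rbind(per_split, frac)
    }
  }
  occ <- colMeans(per_split)
  names(occ) <- as.character(0:R)
  nsplits <- nrow(per_split)
  # SE of the mean over barcodes x splits (Bernoulli per barcode per split)
  se <- sqrt(pmax(occ * (1 - occ), 0) / (n_surv_tot / design$n_outgrowths * nsplits))
  exact <- exact_acc / n_surv_tot
  names(exact) <- names(se) <- as.character(0:R)
  structure(list(occupancy = occ, per_split = per_split, exact = exact,
                 se = se, n_surviving = n_surv_tot / design$n_outgrowths,
                 mean_clone_size = size_sum / n_surv_tot,
                 sizes = sizes_last, n_splits = nsplits),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat("Replicate occupancy of surviving barcodes\n")
  cat(sprintf("  surviving lineages: %.0f (mean size %.1f cells)\n",
              x$n_surviving, x$mean_clone_size))
  df <- data.frame(k = names(x$occupancy),
                   empirical = round(100 * x$occupancy, 3),
                   exact = round(100 * x$exact, 3),
                   se = round(100 * x$se, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
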