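#' Specification of a simulated admixed diploid genome
#'
#' Defaults follow the human-analog study conditions: baseline diploid
#' effective size `1e5`, 5 years per generation, mutation rate `2.5e-8` and
#' recombination rate `5e-9` per site per generation, 100-bp bins. The
#' admixed population's relative size at the admixture time is
#' `admix_ratio = lambda_b / lambda_a` (a `4:1` focal-to-admixed ratio is
#' `admix_ratio = 0.25`); `admix_ratio = 0` or `admix_time_years = 0` gives a
#' single constant-size population.
#'
#' @param n0 Baseline diploid effective population size.
#' @param gen_years Years per generation.
#' @param mu Per-site per-generation mutation rate.
#' @param rec Per-site per-generation recombination rate.
#' @param admix_time_years True admixture time in years (0 = none).
#' @param admix_ratio Admixed-to-focal size ratio `c` (>= 0).
#' @param length_bp Sequence length in bases.
#' @param bin_size Bases per bin.
#' @param seed Optional integer seed for reproducibility.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n0 = 1e5, gen_years = 5, mu = 2.5e-8, rec = 5e-9,
                            admix_time_years = 0, admix_ratio = 0,
                            length_bp = 1e7, bin_size = 100L, seed = NULL) {
  stopifnot(n0 > 0, gen_years > 0, mu > 0, rec > 0,
            admix_time_years >= 0, admix_ratio >= 0, bin_size >= 1,
            length_bp >= bin_size)
  structure(list(n0 = n0, gen_years = gen_years, mu = mu, rec = rec,
                 admix_time_years = admix_time_years,
                 admix_ratio = admix_ratio, length_bp = length_bp,
                 bin_size = as.integer(bin_size), seed = seed),
            class = "simulation_spec")
}

#' Convert between coalescent units and years
#'
#' Coalescent time is measured in units of `2 * N0` generations.
#' @param t Time value(s).
#' @param n0 Diploid baseline effective size.
#' @param gen_years Years per generation.
#' @return The converted time(s).
#' @export
coal_to_years <- function(t, n0, gen_years) t * 2 * n0 * gen_years

#' @rdname coal_to_years
#' @export
years_to_coal <- function(t, n0, gen_years) t / (2 * n0 * gen_years)

# Time grid whose boundary set contains an arbitrary extra time. Used by the
# simulator so that the true admixture time need not sit on the inference
# grid; every interval is its own group.
grid_with_boundary <- function(t_extra, n_intervals = 64L, t_max = 15) {
  base <- time_grid(n_intervals, t_max, paste0(n_intervals, "*1"))
  b <- base$boundaries
  idx <- which(abs(b - t_extra) < 1e-12)
  if (t_extra > 0 && t_extra < t_max && length(idx) == 0L) {
    b <- sort(c(b, t_extra))
  }
  n <- length(b) - 1L
  grid <- structure(
    list(n_intervals = n, boundaries = b, representatives = NULL,
         pattern = paste0(n, "*1"), group_map = seq_len(n),
         n_groups = n, t_max = t_max),
    class = "time_grid")
  grid$representatives <- interval_representatives(grid, rep(1, n))
  grid
}

# Draw a hidden TMRCA-interval path of length L from the HMM (current RNG).
sample_hmm_states <- function(mats, L) {
  n <- nrow(mats$transition)
  cum_t <- apply(mats$transition, 1L, cumsum) # column s = cumulative row s
  cum_t[n, ] <- 1
  sample_path_cpp(cum_t, cumsum(mats$initial), runif(L))
}

# Hidden path plus emitted ternary codes (no missing data).
sample_hmm_obs <- function(mats, L) {
  states <- sample_hmm_states(mats, L)
  as.integer(runif(L) < mats$emission[states, 2])
}

#' Expected heterozygous-bin fraction under a model
#'
#' Closed form `sum_i pi_i * (1 - exp(-theta * t_i))` over the stationary
#' TMRCA distribution and interval representatives; the Monte-Carlo mean of
#' the simulator must match it.
#'
#' @param model An [admixture_model()].
#' @return A probability.
#' @export
expected_het_fraction <- function(model) {
  m <- hmm_matrices(model)
  sum(m$initial * m$emission[, 2])
}

#' Simulate a ternary heterozygosity track with known admixture history
#'
#' The generative process is the model's own sequentially Markovian kernel:
#' physical parameters are converted to per-bin coalescent units
#' (`theta = 4 N0 mu bin`, `rho = 4 N0 rec bin`,
#' `t_a = years / (2 N0 gen_years)`), the true admixture time is inserted as
#' an extra grid boundary (so truth is not aligned to the inference grid),
#' the first TMRCA is drawn from the stationary coalescent prior, successive
#' TMRCAs follow the admixture-aware transition matrix, and each bin emits
#' HET/HOM from the emission model.
#'
#' @param spec A [simulation_spec()].
#' @param n_intervals,t_max Resolution of the simulation grid.
#' @return A `sim_result` list: `sequence` (a [ternary_sequence()]),
#'   `states` (interval index per bin), `tmrca_coal` / `tmrca_years` (true
#'   TMRCA path at interval representatives), the generating `model`,
#'   `theta`, `rho`, `t_a_coal`, and the `spec`.
#' @export
simulate_sequence <- function(spec, n_intervals = 64L, t_max = 15) {
  stopifnot(inherits(spec, "simulation_spec"))
  theta <- 4 * spec$n0 * spec$mu * spec$bin_size
  rho <- 4 * spec$n0 * spec$rec * spec$bin_size
  t_a <- years_to_coal(spec$admix_time_years, spec$n0, spec$gen_years)
  grid <- grid_with_boundary(t_a, n_intervals, t_max)
  k <- if (t_a > 0 && spec$admix_ratio > 0)
    which.min(abs(grid$boundaries - t_a)) - 1L else 0L
  model <- admixture_model(theta = theta, rho = rho, lambda_a = 1,
                           admix_ratio = spec$admix_ratio,
                           t_a_index = k, grid = grid)
  mats <- hmm_matrices(model)
  L <- as.integer(spec$length_bp %/% spec$bin_size)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  states <- sample_hmm_states(mats, L)
  het_p <- mats$emission[, 2]
  obs <- as.integer(runif(L) < het_p[states])
  seq_ <- ternary_sequence(obs, name = "sim", bin_size = spec$bin_size)
  structure(
    list(sequence = seq_, states = states,
         tmrca_coal = mats$representatives[states],
         tmrca_years = coal_to_years(mats$representatives[states],
                                     spec$n0, spec$gen_years),
         model = model, theta = theta, rho = rho, t_a_coal = t_a,
         spec = spec),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d bins, theta = %.3g, rho = %.3g, t_a = %.4g coal (%.1f kya), c = %.3g\n",
              length(x$sequence), x$theta, x$rho, x$t_a_coal,
              x$spec$admix_time_years / 1000, x$spec$admix_ratio))
  invisible(x)
}

#' Run a simulate-and-refit experiment grid
#'
#' For every combination of true admixture time, size ratio and replicate:
#' simulate a genome under [simulate_sequence()], fit it with [smc_fit()],
#' and record the true and estimated admixture times in years. Per-row seeds
#' are drawn reproducibly from `seed`; individual fit failures are recorded
#' in the `error` column rather than aborting the grid.
#'
#' @param times_years True admixture times (years).
#' @param ratios Admixed-to-focal size ratios `c` (a `4:1` design is
#'   `c = 0.25`).
#' @param reps Replicates per (time, ratio) cell.
#' @param base_spec Template [simulation_spec()]; its time/ratio/seed fields
#'   are overwritten per row.
#' @param seed Integer master seed.
#' @param grid Inference [time_grid()] passed to [smc_fit()].
#' @param config [fit_config()] passed to [smc_fit()].
#' @param progress Print one line per completed row?
#' @return A tibble with columns `time_true_years`, `ratio`, `rep`,
#'   `time_est_years`, `loglik`, `converged`, `theta_hat`, `n0_hat`,
#'   `error`.
#' @export
run_experiment_grid <- function(times_years, ratios, reps = 1L,
                                base_spec = simulation_spec(), seed = 1L,
                                grid = time_grid(), config = fit_config(),
                                progress = FALSE) {
  stopifnot(length(times_years) >= 1L, length(ratios) >= 1L, reps >= 1L)
  cells <- tidyr::expand_grid(time_true_years = times_years, ratio = ratios,
                              rep = seq_len(reps))
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  rows <- purrr::pmap(
    list(cells$time_true_years, cells$ratio, cells$rep, row_seeds,
         seq_len(nrow(cells))),
    function(tt, rr, rp, sd, i) {
      out <- tibble::tibble(time_true_years = tt, ratio = rr, rep = rp,
                            time_est_years = NA_real_, loglik = NA_real_,
                            converged = FALSE, theta_hat = NA_real_,
                            n0_hat = NA_real_, error = NA_character_)
      res <- tryCatch({
        spec <- base_spec
        spec$admix_time_years <- tt
        spec$admix_ratio <- rr
        spec$seed <- sd
        sim <- simulate_sequence(spec)
        fit <- smc_fit(sim$sequence, grid = grid, config = config,
                       mu = spec$mu, gen_years = spec$gen_years)
        out$time_est_years <- fit$t_a_years
        out$loglik <- fit$loglik_trace[length(fit$loglik_trace)]
        out$converged <- fit$converged
        out$theta_hat <- fit$theta
        out$n0_hat <- fit$n0_estimate
        out
      }, error = function(e) {
        out$error <- conditionMessage(e)
        out
      })
      if (progress)
        message(sprintf("[%d/%d] true %.1f kya, c = %.3g -> est %.1f kya",
                        i, nrow(cells), tt / 1000, rr,
                        res$time_est_years / 1000))
      res
    })
  dplyr::bind_rows(rows)
}
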